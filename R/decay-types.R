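# Containers for TCSPC data: single-channel decay histograms and polarised
# (parallel/perpendicular) pairs, plus the standard anisotropy combination.

DECAY_CHANNELS <- c("parallel", "perpendicular", "magic_angle", "anisotropy")

#' Construct a TCSPC decay histogram
#'
#' Binned photon counts versus time for one polarisation channel. The time
#' grid must be uniform (half-open bins `[t0, t0 + N dt)`) with at least 64
#' bins. For `channel = "anisotropy"` the values are dimensionless r(t)
#' samples rather than counts and may be negative.
#'
#' @param time_ns uniform increasing time grid, ns.
#' @param counts photon counts (>= 0) or, for the anisotropy channel,
#'   anisotropy values.
#' @param channel one of `"parallel"`, `"perpendicular"`, `"magic_angle"`,
#'   `"anisotropy"`.
#' @return an object of class `decay_histogram`.
#' @export
decay_histogram <- function(time_ns, counts, channel = "magic_angle") {
  check_that(is.numeric(time_ns) && length(time_ns) >= 64,
             "need at least 64 time bins")
  dt <- diff(time_ns)
  check_that(all(dt > 0) && diff(range(dt)) < 1e-9 * max(dt),
             "time grid must be uniform and increasing")
  check_that(length(counts) == length(time_ns),
             "counts must match the time grid")
  channel <- match.arg(channel, DECAY_CHANNELS)
  if (channel != "anisotropy")
    check_that(all(counts >= 0), "counts must be nonnegative")
  structure(list(time_ns = as.numeric(time_ns),
                 counts = as.numeric(counts),
                 channel = channel,
                 dt_ns = mean(dt)),
            class = "decay_histogram")
}

#' Construct a polarised decay pair
#'
#' Parallel and perpendicular TCSPC histograms on identical time grids,
#' with the instrumental G factor correcting the relative detection
#' sensitivity of the two channels.
#'
#' @param parallel,perpendicular [decay_histogram()] objects with channels
#'   `"parallel"` and `"perpendicular"`.
#' @param g_factor instrumental G factor (> 0).
#' @return an object of class `polarized_decay_pair`.
#' @export
polarized_decay_pair <- function(parallel, perpendicular, g_factor = 1) {
  check_that(inherits(parallel, "decay_histogram") &&
               inherits(perpendicular, "decay_histogram"),
             "inputs must be decay_histogram objects")
  check_that(parallel$channel == "parallel" &&
               perpendicular$channel == "perpendicular",
             "channels must be parallel and perpendicular")
  check_that(length(parallel$time_ns) == length(perpendicular$time_ns) &&
               max(abs(parallel$time_ns - perpendicular$time_ns)) < 1e-9,
             "time grids must be identical")
  check_that(is_number(g_factor) && g_factor > 0, "g_factor must be > 0")
  structure(list(parallel = parallel, perpendicular = perpendicular,
                 g_factor = g_factor),
            class = "polarized_decay_pair")
}

#' Total (magic-angle-equivalent) intensity decay from a polarised pair
#'
#' \eqn{S(t) = I_\parallel + 2 G I_\perp} is proportional to the total
#' fluorescence intensity and free of anisotropy weighting, so it carries
#' the pure multi-exponential lifetime information. Because it is a sum of
#' two Poisson channels its variance is \eqn{I_\parallel + 4 G^2 I_\perp},
#' not S; the correct per-bin variance is attached as attribute
#' `"variance"` and honoured by [fit_intensity_decay()].
#'
#' @param pair a [polarized_decay_pair()].
#' @return a [decay_histogram()] with `channel = "magic_angle"`.
#' @export
total_intensity_histogram <- function(pair) {
  check_that(inherits(pair, "polarized_decay_pair"),
             "pair must be a polarized_decay_pair")
  G <- pair$g_factor
  S <- pair$parallel$counts + 2 * G * pair$perpendicular$counts
  out <- decay_histogram(pair$parallel$time_ns, S, "magic_angle")
  attr(out, "variance") <- pmax(pair$parallel$counts +
                                  4 * G^2 * pair$perpendicular$counts, 1)
  out
}

#' Combine polarised decays into an anisotropy trace
#'
#' Per-bin \eqn{r = (I_\parallel - G I_\perp)/(I_\parallel + 2 G I_\perp)}.
#' Bins whose total intensity \eqn{S = I_\parallel + 2 G I_\perp} falls
#' below `intensity_floor` are masked (set to `NA`) because the ratio is
#' dominated by shot noise there. The per-bin standard error of r,
#' propagated from Poisson counting statistics of the two channels, is
#' attached as attribute `"sigma"`; the total intensity as `"total"`.
#'
#' @param pair a [polarized_decay_pair()].
#' @param intensity_floor minimum total intensity for a bin to be reported.
#' @return a [decay_histogram()] with `channel = "anisotropy"`.
#' @export
anisotropy_from_polarized <- function(pair, intensity_floor = 50) {
  check_that(inherits(pair, "polarized_decay_pair"),
             "pair must be a polarized_decay_pair")
  G <- pair$g_factor
  Ipar <- pair$parallel$counts
  Iperp <- pair$perpendicular$counts
  D <- Ipar - G * Iperp
  S <- Ipar + 2 * G * Iperp
  r <- ifelse(S >= intensity_floor & S > 0, D / S, NA_real_)
  # Poisson error propagation: var(r) = (dr/dIpar)^2 Ipar + (dr/dIperp)^2 Iperp
  ok <- !is.na(r)
  sig <- rep(NA_real_, length(r))
  dpar <- (S - D) / S^2
  dperp <- -G * (S + 2 * D) / S^2
  sig[ok] <- sqrt(dpar[ok]^2 * pmax(Ipar[ok], 1) +
                    dperp[ok]^2 * pmax(Iperp[ok], 1))
  out <- decay_histogram(pair$parallel$time_ns, r, channel = "anisotropy")
  attr(out, "sigma") <- sig
  attr(out, "total") <- S
  out
}
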