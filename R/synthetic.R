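# Seeded synthetic-data generators. Every generator is a pure function of
# (preset, grid, noise_spec): the RNG stream is derived from the seed and
# the generator name, drawn locally, and the global RNG state is restored.
# Preset numbers encode the qualitative picture the analysis expects
# (distance ordering 15 < 18 < 25 A, submillimolar K+ affinity, flat Na+
# responses, two-fold NaK2K amplitudes, bi-ionic reversal potentials); they
# are fixtures for recovery testing, not claims about the real proteins.

SCENARIO_NAMES <- c("NaK_K", "NaK_Na", "NaK2K_K", "NaK2K_Na",
                    "KcsA_K_reference")

#' Scenario presets for the synthetic-data generators
#'
#' Returns the full ground-truth parameter set for one of the five built-in
#' scenarios: the two-site channel (NaK) and four-site channel (NaK2K) in
#' K+ or Na+, plus a K+-selective reference channel. Encoded orderings:
#' lateral distances R(NaK2K, K+) = 15 < R(NaK, K+) = 18 < R(Na+) = 25 A;
#' K+ scenarios have finite submillimolar kd and Tm shifts, Na+ scenarios
#' are flat; NaK2K spectroscopic amplitudes are twice NaK's; the four-site
#' channel reverses at +18.6 mV under the standard bi-ionic condition while
#' the two-site channel reverses at 0 mV.
#'
#' @param name one of `"NaK_K"`, `"NaK_Na"`, `"NaK2K_K"`, `"NaK2K_Na"`,
#'   `"KcsA_K_reference"`.
#' @return a list of class `scenario_preset` with components `decay`
#'   (r0, amplitudes, lifetimes, phi_g_ns, R_true_angstrom, R0_angstrom),
#'   `melt` (tm0_C, dtm_C, kd_M, n, dH_kJ, baselines), `hill` (per
#'   observable: s0, ds, kd_M, n), `ephys` (condition, erev_mV,
#'   g_neg_pS, g_pos_pS, flux_plateau, flux_rate_s).
#' @export
scenario_preset <- function(name = SCENARIO_NAMES) {
  name <- match.arg(name)
  base_cond <- bi_ionic_condition()
  p <- switch(
    name,
    NaK_K = list(
      decay = list(r0 = 0.3, amplitudes = c(0.55, 0.45),
                   lifetimes = c(2.8, 6.0), phi_g_ns = 40,
                   R_true_angstrom = 18, R0_angstrom = 13),
      melt = list(tm0_C = 58, dtm_C = 8, kd_M = 5e-4, n = 1, dH_kJ = 350),
      hill = list(
        tm_C = list(s0 = 58, ds = 8, kd_M = 5e-4, n = 1),
        lambda_com_nm = list(s0 = 352, ds = -2, kd_M = 5e-4, n = 1.5),
        r_ss = list(s0 = 0.22, ds = -0.03, kd_M = 5e-4, n = 1.5),
        R_angstrom = list(s0 = 25, ds = -7, kd_M = 5e-4, n = 1.5)),
      ephys = list(cond = base_cond, erev_mV = 0, g_neg_pS = 100,
                   g_pos_pS = 90, flux_plateau = 0.35, flux_rate_s = 0.02)),
    NaK_Na = list(
      decay = list(r0 = 0.3, amplitudes = c(0.6, 0.4),
                   lifetimes = c(2.6, 6.2), phi_g_ns = 40,
                   R_true_angstrom = 25, R0_angstrom = 13),
      melt = list(tm0_C = 58, dtm_C = 0, kd_M = NA_real_, n = 1,
                  dH_kJ = 350),
      hill = list(
        tm_C = list(s0 = 58, ds = 0, kd_M = NA_real_, n = 1),
        lambda_com_nm = list(s0 = 353, ds = 0, kd_M = NA_real_, n = 1.5),
        r_ss = list(s0 = 0.24, ds = 0, kd_M = NA_real_, n = 1.5),
        R_angstrom = list(s0 = 25, ds = 0, kd_M = NA_real_, n = 1.5)),
      ephys = list(cond = base_cond, erev_mV = 0, g_neg_pS = 100,
                   g_pos_pS = 90, flux_plateau = 0.35, flux_rate_s = 0.02)),
    NaK2K_K = list(
      decay = list(r0 = 0.3, amplitudes = c(0.5, 0.5),
                   lifetimes = c(3.0, 6.0), phi_g_ns = 40,
                   R_true_angstrom = 15, R0_angstrom = 13),
      melt = list(tm0_C = 60, dtm_C = 14, kd_M = 3e-4, n = 1, dH_kJ = 400),
      hill = list(
        tm_C = list(s0 = 60, ds = 14, kd_M = 3e-4, n = 1),
        lambda_com_nm = list(s0 = 352, ds = -4, kd_M = 3e-4, n = 1.5),
        r_ss = list(s0 = 0.22, ds = -0.06, kd_M = 3e-4, n = 1.5),
        R_angstrom = list(s0 = 25, ds = -10, kd_M = 3e-4, n = 1.5)),
      ephys = list(cond = base_cond, erev_mV = 18.6, g_neg_pS = 200,
                   g_pos_pS = 50, flux_plateau = 0.15, flux_rate_s = 0.04)),
    NaK2K_Na = list(
      decay = list(r0 = 0.3, amplitudes = c(0.6, 0.4),
                   lifetimes = c(2.6, 6.2), phi_g_ns = 40,
                   R_true_angstrom = 25, R0_angstrom = 13),
      melt = list(tm0_C = 60, dtm_C = 0, kd_M = NA_real_, n = 1,
                  dH_kJ = 400),
      hill = list(
        tm_C = list(s0 = 60, ds = 0, kd_M = NA_real_, n = 1),
        lambda_com_nm = list(s0 = 353, ds = 0, kd_M = NA_real_, n = 1.5),
        r_ss = list(s0 = 0.24, ds = 0, kd_M = NA_real_, n = 1.5),
        R_angstrom = list(s0 = 25, ds = 0, kd_M = NA_real_, n = 1.5)),
      ephys = list(cond = base_cond, erev_mV = 0, g_neg_pS = 100,
                   g_pos_pS = 80, flux_plateau = 0.4, flux_rate_s = 0.015)),
    KcsA_K_reference = list(
      decay = list(r0 = 0.3, amplitudes = c(0.5, 0.5),
                   lifetimes = c(3.0, 6.0), phi_g_ns = 40,
                   R_true_angstrom = 15, R0_angstrom = 12),
      melt = list(tm0_C = 62, dtm_C = 20, kd_M = 1e-5, n = 1, dH_kJ = 450),
      hill = list(
        tm_C = list(s0 = 62, ds = 20, kd_M = 1e-5, n = 1),
        lambda_com_nm = list(s0 = 351, ds = -3, kd_M = 1e-5, n = 1.5),
        r_ss = list(s0 = 0.22, ds = -0.05, kd_M = 1e-5, n = 1.5),
        R_angstrom = list(s0 = 18, ds = -3, kd_M = 1e-5, n = 1.5)),
      ephys = list(cond = base_cond, erev_mV = 56.7, g_neg_pS = 110,
                   g_pos_pS = 100, flux_plateau = 0.2, flux_rate_s = 0.03)))
  p$name <- name
  p$melt$baseline_native <- c(1, -0.003)
  p$melt$baseline_denatured <- c(0.25, -0.001)
  class(p) <- "scenario_preset"
  p
}

resolve_preset <- function(preset) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  check_that(inherits(preset, "scenario_preset"),
             "preset must be a scenario name or scenario_preset object")
  preset
}

# True lateral homo-FRET rate implied by a preset's distance, Forster
# radius and intensity-weighted mean lifetime.
preset_k1 <- function(preset) {
  preset <- resolve_preset(preset)
  d <- preset$decay
  tau2 <- average_lifetimes(d$amplitudes, d$lifetimes)$tau2_int
  k1_from_distance(d$R_true_angstrom, d$R0_angstrom, tau2)
}

#' Noise specification for the generators
#'
#' Defaults encode the stated measurement conditions: TCSPC peak of
#' 2e4 counts, melt noise of 1% of the transition amplitude, titration
#' noise of 0.2 degC (Tm), 0.1 nm (spectral center of mass), 0.002
#' (steady-state anisotropy) and 0.3 A (distance), 0.05 pA on averaged
#' i/V points, and 0.5 a.u. on the flux trace. The seed is mandatory for
#' any stochastic call.
#'
#' @param seed integer seed (mandatory).
#' @param peak_counts expected parallel-channel peak counts.
#' @param melt_sigma_frac melt noise as a fraction of amplitude.
#' @param titration_sigma named list of per-observable sigmas.
#' @param iv_sigma_pA i/V current noise, pA.
#' @param flux_sigma flux-trace noise, a.u.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(seed, peak_counts = 2e4, melt_sigma_frac = 0.01,
                       titration_sigma = list(tm_C = 0.2,
                                              lambda_com_nm = 0.1,
                                              r_ss = 0.002,
                                              R_angstrom = 0.3),
                       iv_sigma_pA = 0.05, flux_sigma = 0.5) {
  check_that(!missing(seed) && is_number(seed),
             "seed is mandatory for any stochastic call")
  check_that(peak_counts > 0 && melt_sigma_frac >= 0 && iv_sigma_pA >= 0 &&
               flux_sigma >= 0, "all noise levels must be >= 0")
  structure(list(seed = as.integer(seed), peak_counts = peak_counts,
                 melt_sigma_frac = melt_sigma_frac,
                 titration_sigma = titration_sigma,
                 iv_sigma_pA = iv_sigma_pA, flux_sigma = flux_sigma),
            class = "noise_spec")
}

#' Simulate a polarised TCSPC pair for a scenario
#'
#' Forward model: the magic-angle intensity decay I(t) follows the preset's
#' multi-exponential lifetimes, the anisotropy r(t) follows
#' [tetramer_anisotropy()] with the preset's true k1 (from its distance via
#' the sixth-power law), and the polarised channels are
#' \eqn{I_\parallel \propto I(1 + 2r)/3}, \eqn{I_\perp \propto I(1 - r)/3},
#' scaled so the expected parallel peak equals `noise$peak_counts`. Counts
#' are independent Poisson draws from a dedicated RNG stream; `noiseless =
#' TRUE` returns the expected counts instead.
#'
#' @param preset scenario name or [scenario_preset()].
#' @param noise a [noise_spec()].
#' @param n_bins,dt_ns histogram geometry (default 1024 bins of 0.05 ns).
#' @param noiseless return expected counts without Poisson noise.
#' @return a [polarized_decay_pair()] with a `"truth"` attribute recording
#'   the generating parameters.
#' @export
gen_tcspc_pair <- function(preset, noise, n_bins = 1024, dt_ns = 0.05,
                           noiseless = FALSE) {
  preset <- resolve_preset(preset)
  check_that(inherits(noise, "noise_spec"), "noise must be a noise_spec")
  d <- preset$decay
  t <- (seq_len(n_bins) - 1) * dt_ns
  k1 <- preset_k1(preset)
  I <- multiexp_intensity(t, d$amplitudes, d$lifetimes)
  r <- tetramer_anisotropy(t, d$r0, k1, d$phi_g_ns)
  epar <- I * (1 + 2 * r) / 3
  eperp <- I * (1 - r) / 3
  scale <- noise$peak_counts / max(epar)
  epar <- epar * scale
  eperp <- eperp * scale
  if (noiseless) {
    cpar <- epar
    cperp <- eperp
  } else {
    cnts <- with_seed(derive_seed(noise$seed, paste0("tcspc_", preset$name)), {
      list(par = stats::rpois(n_bins, epar),
           perp = stats::rpois(n_bins, eperp))
    })
    cpar <- cnts$par
    cperp <- cnts$perp
  }
  pair <- polarized_decay_pair(
    decay_histogram(t, cpar, "parallel"),
    decay_histogram(t, cperp, "perpendicular"),
    g_factor = 1)
  attr(pair, "truth") <- list(
    k1 = k1, r0 = d$r0, phi_g_ns = d$phi_g_ns,
    tau2_int = average_lifetimes(d$amplitudes, d$lifetimes)$tau2_int,
    R_true_angstrom = d$R_true_angstrom, R0_angstrom = d$R0_angstrom)
  pair
}

#' Simulate a pyrene-probe polarised pair for the tumbling-time fit
#'
#' Long-lifetime probe forward model: single ~48 ns intensity decay and a
#' two-term anisotropy \eqn{r(t) = \beta_1 e^{-t/\phi_1} + \beta_2
#' e^{-t/\phi_g}} (fast local wobble plus overall tumbling).
#'
#' @param noise a [noise_spec()].
#' @param phi_g_ns true tumbling time (default 40 ns).
#' @param beta anisotropy amplitudes `c(wobble, tumbling)`.
#' @param phi_wobble_ns fast wobble correlation time.
#' @param tau_ns probe fluorescence lifetime.
#' @param n_bins,dt_ns histogram geometry (256 ns window by default).
#' @param noiseless return expected counts.
#' @return a [polarized_decay_pair()] with `"truth"` attribute.
#' @export
gen_pyrene_pair <- function(noise, phi_g_ns = 40, beta = c(0.05, 0.25),
                            phi_wobble_ns = 1, tau_ns = 48,
                            n_bins = 1024, dt_ns = 0.25, noiseless = FALSE) {
  check_that(inherits(noise, "noise_spec"), "noise must be a noise_spec")
  t <- (seq_len(n_bins) - 1) * dt_ns
  I <- exp(-t / tau_ns)
  r <- beta[1] * exp(-t / phi_wobble_ns) + beta[2] * exp(-t / phi_g_ns)
  epar <- I * (1 + 2 * r) / 3
  eperp <- I * (1 - r) / 3
  scale <- noise$peak_counts / max(epar)
  epar <- epar * scale
  eperp <- eperp * scale
  if (noiseless) {
    cpar <- epar; cperp <- eperp
  } else {
    cnts <- with_seed(derive_seed(noise$seed, "pyrene"), {
      list(par = stats::rpois(n_bins, epar),
           perp = stats::rpois(n_bins, eperp))
    })
    cpar <- cnts$par; cperp <- cnts$perp
  }
  pair <- polarized_decay_pair(
    decay_histogram(t, cpar, "parallel"),
    decay_histogram(t, cperp, "perpendicular"), g_factor = 1)
  attr(pair, "truth") <- list(phi_g_ns = phi_g_ns, beta = beta,
                              phi_wobble_ns = phi_wobble_ns, tau_ns = tau_ns)
  pair
}

# Preset Tm at a given ligand concentration (occupancy law; flat when the
# preset encodes no binding).
preset_tm <- function(preset, conc_M) {
  m <- preset$melt
  if (m$dtm_C == 0 || is.na(m$kd_M)) return(rep(m$tm0_C, length(conc_M)))
  m$tm0_C + m$dtm_C * conc_M^m$n / (m$kd_M^m$n + conc_M^m$n)
}

#' Simulate a ligand series of thermal melt curves
#'
#' One melt curve per concentration: Tm follows the preset's occupancy law
#' (flat for Na+-type presets), the curve is the two-state model with the
#' preset's van't Hoff enthalpy and sloping baselines, and Gaussian noise
#' of `noise$melt_sigma_frac` times the transition amplitude is added.
#'
#' @param preset scenario name or [scenario_preset()].
#' @param conc_M sorted ligand concentrations, M.
#' @param noise a [noise_spec()].
#' @param temperature_C temperature grid (default 30-90 degC in 0.5 steps).
#' @param noiseless disable noise.
#' @return list of [melt_curve()] objects with a `"truth"` attribute
#'   holding the true Tm vector.
#' @export
gen_melt_series <- function(preset, conc_M, noise,
                            temperature_C = seq(30, 90, by = 0.5),
                            noiseless = FALSE) {
  preset <- resolve_preset(preset)
  check_that(inherits(noise, "noise_spec"), "noise must be a noise_spec")
  check_that(!is.unsorted(conc_M) && all(conc_M >= 0),
             "conc_M must be sorted and nonnegative")
  m <- preset$melt
  tms <- preset_tm(preset, conc_M)
  curves <- vector("list", length(conc_M))
  for (i in seq_along(conc_M)) {
    clean <- two_state_melt_model(temperature_C, tms[i], m$dH_kJ,
                                  m$baseline_native, m$baseline_denatured)
    sig <- noise$melt_sigma_frac * diff(range(clean))
    y <- if (noiseless || sig == 0) clean else
      with_seed(derive_seed(noise$seed, paste0("melt_", preset$name, "_", i)),
                clean + stats::rnorm(length(clean), 0, sig))
    curves[[i]] <- melt_curve(temperature_C, y, conc_M[i])
  }
  attr(curves, "truth") <- list(tm_C = tms, dH_kJ = m$dH_kJ,
                                kd_M = m$kd_M, conc_M = conc_M)
  curves
}

#' Simulate a spectroscopic titration series
#'
#' Sigmoidal Hill response of the requested observable with the preset's
#' signed amplitude (negative for the K+-induced blue shift, anisotropy
#' drop and distance contraction; zero for Na+-type presets) plus Gaussian
#' noise. For the two-site channel's spectral center of mass an optional
#' small red-shift above 10 mM (a hydration effect, not binding) can be
#' superimposed with `include_red_shift = TRUE`.
#'
#' @param preset scenario name or [scenario_preset()].
#' @param observable one of `"tm_C"`, `"lambda_com_nm"`, `"r_ss"`,
#'   `"R_angstrom"`.
#' @param conc_M sorted concentrations including a zero anchor; default
#'   zero plus 11 log-spaced points over 3 decades around the transition.
#' @param noise a [noise_spec()].
#' @param include_red_shift superimpose the >10 mM red-shift bump.
#' @param noiseless disable noise.
#' @return a [titration_series()] with a `"truth"` attribute.
#' @export
gen_titration <- function(preset, observable,
                          conc_M = c(0, 10^seq(-5.5, -1.5, length.out = 11)),
                          noise, include_red_shift = FALSE,
                          noiseless = FALSE) {
  preset <- resolve_preset(preset)
  observable <- match.arg(observable, TITRATION_OBSERVABLES)
  check_that(inherits(noise, "noise_spec"), "noise must be a noise_spec")
  h <- preset$hill[[observable]]
  clean <- if (h$ds == 0 || is.na(h$kd_M)) rep(h$s0, length(conc_M))
           else h$s0 + h$ds * conc_M^h$n / (h$kd_M^h$n + conc_M^h$n)
  if (include_red_shift && observable == "lambda_com_nm")
    clean <- clean + 0.6 * conc_M / (conc_M + 0.05)
  sig <- noise$titration_sigma[[observable]]
  y <- if (noiseless || sig == 0) clean else
    with_seed(derive_seed(noise$seed,
                          paste0("titr_", preset$name, "_", observable)),
              clean + stats::rnorm(length(clean), 0, sig))
  out <- titration_series(conc_M, y, observable,
                          stderr = if (sig > 0) rep(sig, length(y)))
  attr(out, "truth") <- h
  out
}

#' Simulate a bi-ionic i/V series
#'
#' Current \eqn{i(V) = g(V)\,(V - E_{rev})} with the conductance blended
#' logistically (width 25 mV) between the preset's negative- and
#' positive-branch values; a hard kink exactly at the reversal would bias
#' interpolation-based reversal extraction, while the blend leaves the
#' branch conductances intact far from E_rev. Gaussian current noise of
#' `noise$iv_sigma_pA` is added per point.
#'
#' @param preset scenario name or [scenario_preset()].
#' @param voltage_mV voltage grid, must bracket the preset reversal
#'   (default -100..100 mV in 10 mV steps).
#' @param noise a [noise_spec()].
#' @param noiseless disable noise.
#' @return an [iv_series()] with a `"truth"` attribute.
#' @export
gen_iv <- function(preset, voltage_mV = seq(-100, 100, by = 10), noise,
                   noiseless = FALSE) {
  preset <- resolve_preset(preset)
  check_that(inherits(noise, "noise_spec"), "noise must be a noise_spec")
  e <- preset$ephys
  check_that(min(voltage_mV) < e$erev_mV && max(voltage_mV) > e$erev_mV,
             "voltage grid must bracket the preset reversal potential")
  g <- e$g_pos_pS + (e$g_neg_pS - e$g_pos_pS) /
    (1 + exp((voltage_mV - e$erev_mV) / 25))
  i <- g * 1e-3 * (voltage_mV - e$erev_mV)
  if (!noiseless && noise$iv_sigma_pA > 0)
    i <- with_seed(derive_seed(noise$seed, paste0("iv_", preset$name)),
                   i + stats::rnorm(length(i), 0, noise$iv_sigma_pA))
  out <- iv_series(voltage_mV, i)
  attr(out, "truth") <- e
  out
}

#' Simulate an ACMA flux trace
#'
#' Flat fluorescence until CCCP addition, then an exponential quench at the
#' preset's flux rate toward a plateau set by `flux_plateau` (fraction of
#' the full span remaining), and a fast drop to the valinomycin floor at
#' the end of the record. Higher channel flux gives a faster, deeper
#' quench.
#'
#' @param preset scenario name or [scenario_preset()].
#' @param noise a [noise_spec()].
#' @param time_s time grid, s.
#' @param t_cccp,t_valinomycin marker times, s.
#' @param plateau_frac optional override of the preset plateau (e.g. 1 for
#'   a zero-flux control).
#' @param noiseless disable noise.
#' @return a [flux_trace()] with a `"truth"` attribute.
#' @export
gen_flux_trace <- function(preset, noise, time_s = seq(0, 600, by = 1),
                           t_cccp = 60, t_valinomycin = 480,
                           plateau_frac = NULL, noiseless = FALSE) {
  preset <- resolve_preset(preset)
  check_that(inherits(noise, "noise_spec"), "noise must be a noise_spec")
  e <- preset$ephys
  p <- if (is.null(plateau_frac)) e$flux_plateau else plateau_frac
  f_top <- 100
  f_floor <- 20
  f_inf <- f_floor + p * (f_top - f_floor)
  f <- rep(f_top, length(time_s))
  quench <- time_s > t_cccp & time_s <= t_valinomycin
  f[quench] <- f_inf + (f_top - f_inf) *
    exp(-(time_s[quench] - t_cccp) * e$flux_rate_s)
  after <- time_s > t_valinomycin
  f_at_val <- f_inf + (f_top - f_inf) *
    exp(-(t_valinomycin - t_cccp) * e$flux_rate_s)
  f[after] <- f_floor + (f_at_val - f_floor) *
    exp(-(time_s[after] - t_valinomycin) * 0.2)
  if (!noiseless && noise$flux_sigma > 0)
    f <- with_seed(derive_seed(noise$seed, paste0("flux_", preset$name)),
                   f + stats::rnorm(length(f), 0, noise$flux_sigma))
  out <- flux_trace(time_s, f, t_cccp, t_valinomycin)
  attr(out, "truth") <- list(plateau = p, rate_s = e$flux_rate_s,
                             f_top = f_top, f_floor = f_floor)
  out
}
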