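# Ligand-linked thermal stability and titration analysis: two-state melt
# fits with sloping baselines, apparent K_D from Tm shifts, and empiric Hill
# fits to any spectroscopic titration observable.

GAS_CONSTANT_J <- 8.314  # J mol^-1 K^-1

TITRATION_OBSERVABLES <- c("tm_C", "lambda_com_nm", "r_ss", "R_angstrom")

#' Construct a thermal melt curve
#'
#' @param temperature_C strictly increasing temperature grid, Celsius,
#'   >= 10 points.
#' @param signal fluorescence at the monitoring wavelength, arbitrary units.
#' @param ligand_conc_M cation concentration of the sample, M.
#' @return an object of class `melt_curve`.
#' @export
melt_curve <- function(temperature_C, signal, ligand_conc_M = 0) {
  check_strictly_increasing(temperature_C, "temperature_C")
  check_that(length(temperature_C) >= 10, "need at least 10 points")
  check_that(length(signal) == length(temperature_C) &&
               all(is.finite(signal)), "signal must match the grid")
  check_that(is_number(ligand_conc_M) && ligand_conc_M >= 0,
             "ligand_conc_M must be >= 0")
  structure(list(temperature_C = as.numeric(temperature_C),
                 signal = as.numeric(signal),
                 ligand_conc_M = ligand_conc_M),
            class = "melt_curve")
}

#' Construct a titration series
#'
#' A spectroscopic observable measured across ligand concentrations,
#' including a zero/blank anchor.
#'
#' @param ligand_conc_M nonnegative sorted concentrations, >= 5 values.
#' @param value observable values.
#' @param observable one of `"tm_C"`, `"lambda_com_nm"`, `"r_ss"`,
#'   `"R_angstrom"`.
#' @param stderr optional per-point standard errors.
#' @return an object of class `titration_series`.
#' @export
titration_series <- function(ligand_conc_M, value, observable,
                             stderr = NULL) {
  check_that(is.numeric(ligand_conc_M) && length(ligand_conc_M) >= 5,
             "need at least 5 concentrations")
  check_that(all(ligand_conc_M >= 0) && !is.unsorted(ligand_conc_M),
             "concentrations must be nonnegative and sorted")
  check_that(length(value) == length(ligand_conc_M),
             "value must match the concentration grid")
  observable <- match.arg(observable, TITRATION_OBSERVABLES)
  if (!is.null(stderr))
    check_that(length(stderr) == length(value) && all(stderr > 0),
               "stderr must be positive and match the grid")
  structure(list(ligand_conc_M = as.numeric(ligand_conc_M),
                 value = as.numeric(value), observable = observable,
                 stderr = stderr),
            class = "titration_series")
}

#' Two-state thermal unfolding model with linear baselines
#'
#' Van't Hoff two-state equilibrium: \eqn{K(T) = \exp[-\Delta H_{vH}(1 -
#' T/T_m)/(RT)]} (temperatures in Kelvin internally, \eqn{\Delta C_p = 0}),
#' unfolded fraction \eqn{f_U = K/(1+K)}, and observed signal
#' \eqn{(1-f_U)(a_N + b_N T) + f_U(a_D + b_D T)} with pre- and
#' post-transition baselines linear in temperature (Celsius).
#'
#' @param temperature_C temperature grid, Celsius.
#' @param tm_C midpoint temperature, Celsius.
#' @param dH_vH van't Hoff enthalpy, kJ/mol (> 0).
#' @param baseline_native,baseline_denatured `c(intercept, slope)` of the
#'   two baselines (signal vs Celsius).
#' @return expected signal on the grid.
#' @export
two_state_melt_model <- function(temperature_C, tm_C, dH_vH,
                                 baseline_native = c(1, 0),
                                 baseline_denatured = c(0, 0)) {
  check_that(is_number(tm_C), "tm_C must be numeric")
  check_that(is_number(dH_vH) && dH_vH > 0, "dH_vH must be positive")
  fU <- unfolded_fraction(temperature_C, tm_C, dH_vH)
  native <- baseline_native[1] + baseline_native[2] * temperature_C
  denat <- baseline_denatured[1] + baseline_denatured[2] * temperature_C
  (1 - fU) * native + fU * denat
}

unfolded_fraction <- function(temperature_C, tm_C, dH_vH) {
  TK <- temperature_C + 273.15
  TmK <- tm_C + 273.15
  K <- exp(-dH_vH * 1000 * (1 - TK / TmK) / (GAS_CONSTANT_J * TK))
  K / (1 + K)
}

#' Fit a two-state melt curve
#'
#' Weighted least squares with the midpoint temperature and van't Hoff
#' enthalpy optimised nonlinearly and the four baseline coefficients solved
#' by variable projection. The fit is flagged (`edge_flag`) when the fitted
#' Tm lies within 2 degC of either end of the data, and reported as a
#' flagged failure (`ok = FALSE`, `no_transition`) when no transition is
#' detectable above the noise floor.
#'
#' @param curve a [melt_curve()].
#' @param weights optional per-point weights (default uniform).
#' @return an object of class `two_state_melt_fit`: `tm_C`, `dH_vH`
#'   (kJ/mol), baselines, `chi2r`, `stderr`, flags.
#' @export
fit_melt <- function(curve, weights = NULL) {
  check_that(inherits(curve, "melt_curve"), "curve must be a melt_curve")
  Tc <- curve$temperature_C
  y <- curve$signal
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  rng <- range(Tc)
  # transition visibility: the smoothed signal span must exceed the noise
  # floor (running mean suppresses the noise so a flat-but-noisy curve is
  # not mistaken for a transition)
  noise <- stats::sd(diff(y)) / sqrt(2)
  sm <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  if (diff(range(sm, na.rm = TRUE)) < 5 * max(noise, 1e-12)) {
    return(structure(list(ok = FALSE, no_transition = TRUE,
                          message = "no transition detected above noise"),
                     class = "two_state_melt_fit"))
  }
  basis_fn <- function(theta) {
    fU <- unfolded_fraction(Tc, theta[1], exp(theta[2]))
    cbind(nat_a = 1 - fU, nat_b = (1 - fU) * Tc, den_a = fU, den_b = fU * Tc)
  }
  # Tm start: temperature at which the signal crosses its midrange
  mid <- (max(y) + min(y)) / 2
  cross <- Tc[which.min(abs(y - mid))]
  starts <- list(c(cross, log(200)), c(cross, log(400)), c(cross, log(600)),
                 c(mean(rng), log(400)), c(cross, log(100)))
  fit <- varpro_fit(y, w, basis_fn, starts,
                    lower = c(rng[1], log(10)), upper = c(rng[2], log(5000)),
                    theta_names = c("tm_C", "log_dH"),
                    coef_names = c("nat_a", "nat_b", "den_a", "den_b"))
  if (!isTRUE(fit$ok))
    return(structure(list(ok = FALSE, no_transition = FALSE,
                          message = fit$message),
                     class = "two_state_melt_fit"))
  tm <- unname(fit$theta[1])
  structure(list(ok = TRUE, tm_C = tm, dH_vH = exp(unname(fit$theta[2])),
                 baseline_native = unname(fit$coef[1:2]),
                 baseline_denatured = unname(fit$coef[3:4]),
                 chi2r = fit$chi2r, stderr = fit$stderr,
                 edge_flag = tm < rng[1] + 2 || tm > rng[2] - 2,
                 ligand_conc_M = curve$ligand_conc_M,
                 no_transition = FALSE),
            class = "two_state_melt_fit")
}

#' @export
print.two_state_melt_fit <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat("Melt fit FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("Two-state melt fit: tm = %.2f degC, dH_vH = %.0f kJ/mol, chi2r = %.3f\n",
              x$tm_C, x$dH_vH, x$chi2r))
  if (isTRUE(x$edge_flag))
    cat("  NOTE: tm within 2 degC of the data edge - poorly constrained\n")
  invisible(x)
}

#' Empiric Hill fit to a titration observable
#'
#' \eqn{S([L]) = s_0 + \Delta s \cdot [L]^n/(K_D^n + [L]^n)} with signed
#' amplitude, fitted in linear concentration (so a zero anchor is handled
#' naturally) with kd and n optimised on log scale and the endpoints solved
#' linearly. Reports the apparent dissociation constant, Hill coefficient,
#' the 95% saturation concentration \eqn{[L]_{95} = K_D \cdot 19^{1/n}},
#' and a `no_binding` flag when the realised amplitude does not exceed
#' 5x the residual noise (the flat Na+-titration case).
#'
#' @param series a [titration_series()].
#' @param n_hill `"free"` or a fixed positive value (e.g. `1` for the
#'   single-set-of-sites reading).
#' @param conc_cutoff_M optional upper concentration cutoff excluding
#'   points above it (e.g. to drop the >10 mM hydration red-shift of the
#'   two-site channel); default `Inf` keeps everything.
#' @return an object of class `hill_fit`: `kd_app_M`, `n_hill`, `s0`, `ds`,
#'   `l95_M`, `chi2r`, `stderr`, `no_binding`, `ok`.
#' @export
hill_fit <- function(series, n_hill = "free", conc_cutoff_M = Inf) {
  check_that(inherits(series, "titration_series"),
             "series must be a titration_series")
  keep <- series$ligand_conc_M <= conc_cutoff_M
  L <- series$ligand_conc_M[keep]
  y <- series$value[keep]
  check_that(length(L) >= 5, "need at least 5 points below the cutoff")
  w <- if (is.null(series$stderr)) rep(1, length(y))
       else 1 / series$stderr[keep]^2
  pos <- L[L > 0]
  n_free <- identical(n_hill, "free")
  if (!n_free)
    check_that(is_number(n_hill) && n_hill > 0, "fixed n_hill must be > 0")
  hill_term <- function(kd, n) L^n / (kd^n + L^n)
  basis_fn <- function(theta) {
    kd <- exp(theta[1])
    n <- if (n_free) exp(theta[2]) else n_hill
    cbind(s0 = 1, ds = hill_term(kd, n))
  }
  kd_starts <- exp(seq(log(min(pos)), log(max(pos)), length.out = 5))
  starts <- lapply(kd_starts, function(k) {
    if (n_free) c(log(k), log(1)) else log(k)
  })
  lower <- c(log(min(pos)) - 4, if (n_free) log(0.2))
  upper <- c(log(max(pos)) + 4, if (n_free) log(6))
  fit <- varpro_fit(y, w, basis_fn, starts, lower, upper,
                    theta_names = c("log_kd", if (n_free) "log_n"),
                    coef_names = c("s0", "ds"))
  if (!isTRUE(fit$ok))
    return(structure(list(ok = FALSE, message = fit$message),
                     class = "hill_fit"))
  kd <- exp(unname(fit$theta[1]))
  n <- if (n_free) exp(unname(fit$theta[2])) else n_hill
  s0 <- unname(fit$coef[1])
  ds <- unname(fit$coef[2])
  sigma_hat <- sqrt(fit$rss / fit$dof / stats::median(w))
  no_binding <- abs(ds) < 5 * sigma_hat
  wide_ci <- !is.na(fit$stderr["log_kd"]) && fit$stderr[["log_kd"]] > 1
  # unconstrained plateau: top of the curve not reached within the data
  plateau_unconstrained <- max(L) < kd * 19^(1 / n)
  if (!no_binding && plateau_unconstrained)
    warning("saturation plateau not reached within the data; kd poorly constrained",
            call. = FALSE)
  structure(list(ok = TRUE, kd_app_M = kd, n_hill = n, s0 = s0, ds = ds,
                 l95_M = kd * 19^(1 / n), chi2r = fit$chi2r,
                 stderr = fit$stderr, sigma_hat = sigma_hat,
                 no_binding = no_binding,
                 wide_ci_flag = wide_ci || plateau_unconstrained,
                 observable = series$observable,
                 n_fixed = !n_free),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat("Hill fit FAILED:", x$message, "\n")
    return(invisible(x))
  }
  if (isTRUE(x$no_binding)) {
    cat(sprintf("Hill fit (%s): no binding detected (amplitude below noise)\n",
                x$observable))
    return(invisible(x))
  }
  cat(sprintf("Hill fit (%s): kd_app = %.3g M, n = %.2f%s, ds = %.3g, chi2r = %.3f\n",
              x$observable, x$kd_app_M, x$n_hill,
              if (x$n_fixed) " (fixed)" else "", x$ds, x$chi2r))
  cat(sprintf("  95%% saturation at %.3g M\n", x$l95_M))
  if (isTRUE(x$wide_ci_flag))
    cat("  NOTE: kd poorly constrained (wide interval or unreached plateau)\n")
  invisible(x)
}

#' Apparent K_D from ligand-dependent Tm shifts
#'
#' The Tm increase with ligand concentration tracks site occupancy, so the
#' ligand dependence \eqn{t_m([L]) = t_{m,0} + \Delta t_m [L]^n/(K_D^n +
#' [L]^n)} yields an apparent dissociation constant. This is [hill_fit()]
#' specialised to the `tm_C` observable; `n_hill = 1` gives the
#' single-set-of-sites reading. A flat (Na+-like) series is reported with
#' `no_binding = TRUE` and an undefined kd.
#'
#' @param series a [titration_series()] with observable `"tm_C"`.
#' @param n_hill `"free"` or fixed value.
#' @return a `hill_fit` object.
#' @export
fit_tm_titration <- function(series, n_hill = "free") {
  check_that(inherits(series, "titration_series") &&
               series$observable == "tm_C",
             "series must be a tm_C titration_series")
  pos <- series$ligand_conc_M[series$ligand_conc_M > 0]
  if (log10(max(pos) / min(pos)) < 2)
    warning("concentration grid spans less than two decades", call. = FALSE)
  fit <- hill_fit(series, n_hill = n_hill)
  if (isTRUE(fit$ok) && !isTRUE(fit$no_binding) && fit$ds < 0)
    warning("fitted Tm shift is negative; destabilisation is not the expected binding signature",
            call. = FALSE)
  fit
}

#' Consistency report across per-observable K_D estimates
#'
#' Under a single-binding-event scheme (vacant filter to conductive,
#' K+-loaded filter) every observable should report the same apparent K_D.
#' Aggregates a set of Hill fits, returns the geometric mean and spread of
#' their kd values, and raises a consistency flag when any two disagree by
#' more than `flag_ratio` (default 3x).
#'
#' @param fits list of `hill_fit` objects (>= 2 with binding detected).
#' @param flag_ratio disagreement ratio that triggers the flag.
#' @return list with `kd_values`, `kd_geomean_M`, `spread_ratio`,
#'   `consistent`, `flag`.
#' @export
single_binding_scheme_report <- function(fits, flag_ratio = 3) {
  check_that(is.list(fits) && length(fits) >= 2,
             "need at least 2 fits")
  ok <- vapply(fits, function(f) isTRUE(f$ok) && !isTRUE(f$no_binding),
               logical(1))
  kd <- vapply(fits[ok], function(f) f$kd_app_M, numeric(1))
  names(kd) <- vapply(fits[ok], function(f)
    if (is.null(f$observable)) "?" else f$observable, character(1))
  if (length(kd) < 2)
    return(list(kd_values = kd, kd_geomean_M = NA_real_,
                spread_ratio = NA_real_, consistent = NA,
                flag = "fewer than two binding-detected fits"))
  spread <- max(kd) / min(kd)
  list(kd_values = kd,
       kd_geomean_M = exp(mean(log(kd))),
       spread_ratio = spread,
       consistent = spread <= flag_ratio,
       flag = if (spread > flag_ratio) "kd estimates disagree by more than 3x"
              else NULL)
}
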