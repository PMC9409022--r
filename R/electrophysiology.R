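# Bi-ionic GHK permeability analysis, reversal-potential extraction from
# i/V series, slope conductance, and ACMA flux-trace normalisation.

FARADAY_C <- 96485    # C mol^-1

#' Bi-ionic recording condition
#'
#' The four monovalent cation concentrations and temperature entering the
#' two-ion Goldman-Hodgkin-Katz relation. Defaults are the standard
#' bi-ionic protocol: 200 mM K+ bath (outside), 20 mM K+ / 180 mM Na+
#' pipette (inside), 297 K.
#'
#' @param k_out_mM,na_out_mM,k_in_mM,na_in_mM concentrations, mM (>= 0).
#' @param temperature_K absolute temperature, in `[273, 320]`.
#' @return an object of class `bi_ionic_condition`.
#' @export
bi_ionic_condition <- function(k_out_mM = 200, na_out_mM = 0,
                               k_in_mM = 20, na_in_mM = 180,
                               temperature_K = 297) {
  conc <- c(k_out_mM, na_out_mM, k_in_mM, na_in_mM)
  check_that(all(is.finite(conc)) && all(conc >= 0),
             "concentrations must be finite and >= 0")
  check_that(k_out_mM + na_out_mM > 0 && k_in_mM + na_in_mM > 0,
             "each side needs at least one nonzero cation")
  check_that(is_number(temperature_K) && temperature_K >= 273 &&
               temperature_K <= 320, "temperature must lie in [273, 320] K")
  structure(list(k_out_mM = k_out_mM, na_out_mM = na_out_mM,
                 k_in_mM = k_in_mM, na_in_mM = na_in_mM,
                 temperature_K = temperature_K),
            class = "bi_ionic_condition")
}

#' GHK reversal potential for a given Na+/K+ permeability ratio
#'
#' \deqn{E_{rev} = \frac{RT}{F}\ln\frac{[K]_o + x[Na]_o}{[K]_i + x[Na]_i}}
#' with \eqn{x = P_{Na}/P_K}; only the two monovalent cations enter the
#' printed bi-ionic form. R = 8.314 J mol^-1 K^-1, F = 96485 C mol^-1.
#'
#' @param p_na_over_pk permeability ratio x (>= 0).
#' @param cond a [bi_ionic_condition()].
#' @return reversal potential, mV.
#' @export
ghk_reversal <- function(p_na_over_pk, cond = bi_ionic_condition()) {
  check_that(all(p_na_over_pk >= 0), "permeability ratio must be >= 0")
  check_that(inherits(cond, "bi_ionic_condition"),
             "cond must be a bi_ionic_condition")
  num <- cond$k_out_mM + p_na_over_pk * cond$na_out_mM
  den <- cond$k_in_mM + p_na_over_pk * cond$na_in_mM
  check_that(all(num > 0) && all(den > 0),
             "GHK numerator/denominator must be positive")
  rt_f_mV(cond$temperature_K) * log(num / den)
}

rt_f_mV <- function(temperature_K)
  1000 * GAS_CONSTANT_J * temperature_K / FARADAY_C

#' Na+/K+ permeability ratio from a measured reversal potential
#'
#' Closed-form inversion of the bi-ionic GHK relation:
#' \deqn{x = \frac{[K]_o - e^{FE/RT}[K]_i}{e^{FE/RT}[Na]_i - [Na]_o}}
#' Round-trips with [ghk_reversal()] to machine precision. A negative
#' algebraic solution means the measured potential lies outside the GHK
#' regime for these concentrations and is returned as `NA` with a warning.
#'
#' @param erev_mV measured reversal potential, mV.
#' @param cond a [bi_ionic_condition()].
#' @return permeability ratio P_Na/P_K (dimensionless).
#' @export
permeability_ratio_from_erev <- function(erev_mV,
                                         cond = bi_ionic_condition()) {
  check_that(is_number(erev_mV), "erev_mV must be a single number")
  check_that(inherits(cond, "bi_ionic_condition"),
             "cond must be a bi_ionic_condition")
  ef <- exp(erev_mV / rt_f_mV(cond$temperature_K))
  den <- ef * cond$na_in_mM - cond$na_out_mM
  check_that(den != 0, "degenerate condition: Na+ terms cancel")
  x <- (cond$k_out_mM - ef * cond$k_in_mM) / den
  if (x < 0 && x > -1e-10) x <- 0   # roundoff at the Nernst limit
  if (x < 0) {
    warning("negative permeability ratio: reversal potential outside the GHK regime",
            call. = FALSE)
    return(NA_real_)
  }
  x
}

#' Construct an i/V series
#'
#' @param voltage_mV sorted holding potentials, mV, >= 4 points.
#' @param current_pA currents, pA.
#' @param stderr optional per-point errors, pA.
#' @return an object of class `iv_series`.
#' @export
iv_series <- function(voltage_mV, current_pA, stderr = NULL) {
  check_that(is.numeric(voltage_mV) && length(voltage_mV) >= 4,
             "need at least 4 voltage points")
  check_that(!is.unsorted(voltage_mV, strictly = TRUE),
             "voltages must be strictly increasing")
  check_that(length(current_pA) == length(voltage_mV),
             "currents must match voltages")
  structure(list(voltage_mV = as.numeric(voltage_mV),
                 current_pA = as.numeric(current_pA), stderr = stderr),
            class = "iv_series")
}

#' Reversal potential from an i/V series
#'
#' The null-current potential is the x-axis crossing of the i/V relation:
#' linear interpolation between the two points bracketing zero current, or
#' optionally the root of a local linear regression over the bracketing
#' points plus/minus `local_window` neighbours.
#'
#' @param iv an [iv_series()] whose currents change sign.
#' @param method `"interpolate"` (default) or `"local_regression"`.
#' @param local_window neighbours on each side for the local regression.
#' @return reversal potential, mV.
#' @export
reversal_from_iv <- function(iv, method = c("interpolate", "local_regression"),
                             local_window = 2) {
  check_that(inherits(iv, "iv_series"), "iv must be an iv_series")
  method <- match.arg(method)
  v <- iv$voltage_mV
  i <- iv$current_pA
  sgn <- sign(i)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 &
                   (sgn[-1] != 0 | sgn[-length(sgn)] != 0))
  if (any(i == 0)) return(v[which(i == 0)[1]])
  check_that(length(cross) >= 1,
             "currents do not bracket zero: no reversal in the series")
  j <- cross[1]
  if (method == "interpolate") {
    v[j] - i[j] * (v[j + 1] - v[j]) / (i[j + 1] - i[j])
  } else {
    idx <- max(1, j - local_window + 1):min(length(v), j + local_window)
    fit <- stats::lm(i[idx] ~ v[idx])
    -stats::coef(fit)[[1]] / stats::coef(fit)[[2]]
  }
}

#' Slope conductance on one branch of an i/V series
#'
#' Least-squares slope of current versus voltage restricted to negative or
#' positive holding potentials, reported in pS (1 pA/mV = 1000 pS). The
#' ratio of negative- to positive-branch conductances is the inward
#' rectification index.
#'
#' @param iv an [iv_series()].
#' @param branch `"negative"` or `"positive"` voltages.
#' @return slope conductance, pS.
#' @export
slope_conductance <- function(iv, branch = c("negative", "positive")) {
  check_that(inherits(iv, "iv_series"), "iv must be an iv_series")
  branch <- match.arg(branch)
  sel <- if (branch == "negative") iv$voltage_mV < 0 else iv$voltage_mV > 0
  check_that(sum(sel) >= 3, "need at least 3 points on the requested branch")
  v <- iv$voltage_mV[sel]
  i <- iv$current_pA[sel]
  unname(stats::coef(stats::lm(i ~ v))[2]) * 1000
}

#' @rdname slope_conductance
#' @return `rectification_index`: conductance ratio g(-)/g(+).
#' @export
rectification_index <- function(iv) {
  slope_conductance(iv, "negative") / slope_conductance(iv, "positive")
}

#' Construct an ACMA flux trace
#'
#' Fluorescence versus time from the liposome flux assay, with the CCCP
#' (flux start) and valinomycin (full equilibration) addition times marked.
#'
#' @param time_s increasing time grid, s.
#' @param fluorescence fluorescence, arbitrary units.
#' @param t_cccp,t_valinomycin marker times, `t_cccp < t_valinomycin`.
#' @return an object of class `flux_trace`.
#' @export
flux_trace <- function(time_s, fluorescence, t_cccp, t_valinomycin) {
  check_strictly_increasing(time_s, "time_s")
  check_that(length(fluorescence) == length(time_s),
             "fluorescence must match the time grid")
  check_that(is_number(t_cccp) && is_number(t_valinomycin) &&
               t_cccp < t_valinomycin,
             "need t_cccp < t_valinomycin")
  check_that(t_cccp >= min(time_s) && t_valinomycin <= max(time_s),
             "markers must lie within the record")
  structure(list(time_s = as.numeric(time_s),
                 fluorescence = as.numeric(fluorescence),
                 t_cccp = t_cccp, t_valinomycin = t_valinomycin),
            class = "flux_trace")
}

#' Normalise an ACMA flux trace to the CCCP/valinomycin span
#'
#' \eqn{\hat F = (F - F_{min})/(F_{max} - F_{min})} where the maximum is
#' the fluorescence at CCCP addition and the minimum the floor reached
#' after valinomycin, so the normalised trace is 1 at flux start and 0 at
#' full equilibration.
#'
#' @param trace a [flux_trace()].
#' @return a `flux_trace` with normalised fluorescence in `[0, 1]`.
#' @export
normalize_flux_trace <- function(trace) {
  check_that(inherits(trace, "flux_trace"), "trace must be a flux_trace")
  f_cccp <- interp_linear(trace$time_s, trace$fluorescence, trace$t_cccp)
  f_val <- min(trace$fluorescence[trace$time_s >= trace$t_valinomycin])
  check_that(abs(f_cccp - f_val) > 1e-12,
             "degenerate span: CCCP and valinomycin fluorescence coincide")
  out <- trace
  out$fluorescence <- (trace$fluorescence - f_val) / (f_cccp - f_val)
  out
}
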