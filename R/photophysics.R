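# Spectral computations for the tryptophan homo-FRET ruler: emission center
# of mass, relative quantum yield, overlap integral J, Forster radius R0,
# FRET efficiency and the distance-detection window.

#' Construct an emission spectrum
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm), length >= 2.
#' @param intensity nonnegative fluorescence intensities (arbitrary units).
#' @return an object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelength_nm, intensity) {
  check_strictly_increasing(wavelength_nm, "wavelength_nm")
  check_that(is.numeric(intensity) && length(intensity) == length(wavelength_nm),
             "intensity must match the wavelength grid")
  check_that(all(is.finite(intensity)) && all(intensity >= 0),
             "intensities must be finite and nonnegative")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 intensity = as.numeric(intensity)),
            class = "emission_spectrum")
}

#' Construct an absorption spectrum
#'
#' @param wavelength_nm strictly increasing wavelength grid (nm).
#' @param epsilon molar extinction coefficients (M^-1 cm^-1), nonnegative.
#' @return an object of class `absorption_spectrum`.
#' @export
absorption_spectrum <- function(wavelength_nm, epsilon) {
  check_strictly_increasing(wavelength_nm, "wavelength_nm")
  check_that(is.numeric(epsilon) && length(epsilon) == length(wavelength_nm),
             "epsilon must match the wavelength grid")
  check_that(all(is.finite(epsilon)) && all(epsilon >= 0),
             "epsilon must be finite and nonnegative")
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 epsilon = as.numeric(epsilon)),
            class = "absorption_spectrum")
}

#' Forster-theory parameter bundle
#'
#' Holds the orientation factor kappa^2, medium refractive index, donor
#' quantum yield and overlap integral entering the Forster radius. Defaults
#' are the dynamic isotropic limit kappa^2 = 2/3 and n = 1.6 appropriate for
#' a tryptophan buried in a protein/detergent complex.
#'
#' @param kappa2 orientation factor, in (0, 4].
#' @param n_refr refractive index, > 1.
#' @param phi_d donor quantum yield, in (0, 1].
#' @param J overlap integral in M^-1 cm^-1 nm^4, >= 0.
#' @return an object of class `forster_params`.
#' @export
forster_params <- function(kappa2 = 2/3, n_refr = 1.6, phi_d, J) {
  check_that(is_number(kappa2) && kappa2 > 0 && kappa2 <= 4,
             "kappa2 must lie in (0, 4]")
  check_that(is_number(n_refr) && n_refr > 1, "n_refr must exceed 1")
  check_that(is_number(phi_d) && phi_d > 0 && phi_d <= 1,
             "phi_d must lie in (0, 1]")
  check_that(is_number(J) && J >= 0, "J must be >= 0")
  structure(list(kappa2 = kappa2, n_refr = n_refr, phi_d = phi_d, J = J),
            class = "forster_params")
}

#' Intensity-weighted average emission wavelength (spectral center of mass)
#'
#' Computes \eqn{\langle\lambda\rangle = \int \lambda I(\lambda) d\lambda /
#' \int I(\lambda) d\lambda} by trapezoidal quadrature on the spectrum's own
#' grid. This is the observable whose K+-induced blue shift reports on
#' burial of the pore-helix tryptophan.
#'
#' @param spectrum an [emission_spectrum()].
#' @return center-of-mass wavelength in nm.
#' @export
spectral_center_of_mass <- function(spectrum) {
  check_that(inherits(spectrum, "emission_spectrum"),
             "spectrum must be an emission_spectrum")
  lam <- spectrum$wavelength_nm
  I <- spectrum$intensity
  area <- trapz(lam, I)
  check_that(area > 0, "spectrum has zero total intensity")
  trapz(lam, lam * I) / area
}

#' Relative quantum yield against a reference fluorophore
#'
#' Dilute-limit comparative method: \eqn{\Phi = \Phi_{ref} \cdot
#' (A_s/A_{ref}) \cdot (abs_{ref}/abs_s)} where A are integrated emission
#' areas and abs the absorbances at the excitation wavelength. The
#' conventional reference is N-acetyl-L-tryptophanamide in water
#' (phi_ref = 0.14). Values above 1 are clipped with a warning (the raw
#' value is kept in the `"raw"` attribute); absorbances above 0.1 trigger a
#' dilute-limit warning.
#'
#' @param sample_em,ref_em emission spectra of sample and reference.
#' @param sample_abs,ref_abs absorbances at the excitation wavelength.
#' @param phi_ref reference quantum yield.
#' @return quantum yield (fraction).
#' @export
quantum_yield_relative <- function(sample_em, sample_abs, ref_em, ref_abs,
                                   phi_ref = 0.14) {
  check_that(inherits(sample_em, "emission_spectrum") &&
               inherits(ref_em, "emission_spectrum"),
             "spectra must be emission_spectrum objects")
  check_that(is_number(sample_abs) && sample_abs > 0 &&
               is_number(ref_abs) && ref_abs > 0,
             "absorbances must be positive")
  if (sample_abs > 0.1 || ref_abs > 0.1)
    warning("absorbance above 0.1: outside the dilute limit", call. = FALSE)
  area_s <- trapz(sample_em$wavelength_nm, sample_em$intensity)
  area_r <- trapz(ref_em$wavelength_nm, ref_em$intensity)
  check_that(area_r > 0, "reference spectrum has zero area")
  check_that(area_s > 0, "sample spectrum has zero area")
  phi <- phi_ref * (area_s / area_r) * (ref_abs / sample_abs)
  if (phi > 1) {
    warning(sprintf("quantum yield %.3f > 1; clipped to 1", phi),
            call. = FALSE)
    return(structure(1, raw = phi))
  }
  phi
}

#' Spectral overlap integral J
#'
#' \eqn{J = \int \hat F_D(\lambda)\,\varepsilon(\lambda)\,\lambda^4
#' d\lambda} with the donor emission internally normalised to unit area.
#' Both spectra are linearly interpolated onto the union of their grids
#' restricted to the overlapping wavelength interval, and integrated by the
#' trapezoidal rule. Units: M^-1 cm^-1 nm^4 (the only unit system consistent
#' with the 0.2108 prefactor of [forster_radius()] yielding Angstroms).
#'
#' @param donor_em donor [emission_spectrum()].
#' @param acceptor_abs acceptor [absorption_spectrum()].
#' @return overlap integral J in M^-1 cm^-1 nm^4.
#' @export
spectral_overlap <- function(donor_em, acceptor_abs) {
  check_that(inherits(donor_em, "emission_spectrum"),
             "donor_em must be an emission_spectrum")
  check_that(inherits(acceptor_abs, "absorption_spectrum"),
             "acceptor_abs must be an absorption_spectrum")
  lo <- max(min(donor_em$wavelength_nm), min(acceptor_abs$wavelength_nm))
  hi <- min(max(donor_em$wavelength_nm), max(acceptor_abs$wavelength_nm))
  check_that(lo < hi, "donor and acceptor wavelength ranges do not overlap")
  grid <- sort(unique(c(
    donor_em$wavelength_nm[donor_em$wavelength_nm >= lo &
                             donor_em$wavelength_nm <= hi],
    acceptor_abs$wavelength_nm[acceptor_abs$wavelength_nm >= lo &
                                 acceptor_abs$wavelength_nm <= hi],
    lo, hi)))
  fd <- interp_linear(donor_em$wavelength_nm, donor_em$intensity, grid)
  eps <- interp_linear(acceptor_abs$wavelength_nm, acceptor_abs$epsilon, grid)
  # normalise donor over its FULL emission band, not just the overlap window
  area <- trapz(donor_em$wavelength_nm, donor_em$intensity)
  check_that(area > 0, "donor spectrum has zero area")
  trapz(grid, fd / area * eps * grid^4)
}

#' Forster radius from photophysical parameters
#'
#' \eqn{R_0 = 0.2108\,[\kappa^2 n^{-4} \Phi_D J]^{1/6}} with J in
#' M^-1 cm^-1 nm^4, giving R0 in Angstroms; R0 is the donor-acceptor
#' separation at which transfer efficiency is 50% for an isolated pair.
#'
#' @param p a [forster_params()] bundle.
#' @return Forster radius in Angstroms.
#' @export
forster_radius <- function(p) {
  check_that(inherits(p, "forster_params"), "p must be forster_params")
  check_that(p$J > 0, "R0 undefined for J = 0")
  0.2108 * (p$kappa2 * p$n_refr^-4 * p$phi_d * p$J)^(1/6)
}

#' FRET efficiency of an isolated donor-acceptor pair
#'
#' \eqn{E = 1/(1 + (R/R_0)^6)}; strictly decreasing in R, and E = 1/2 at
#' R = R0 by definition of the Forster radius.
#'
#' @param R donor-acceptor distance, Angstroms (> 0).
#' @param R0 Forster radius, Angstroms (> 0).
#' @return transfer efficiency (fraction).
#' @export
fret_efficiency <- function(R, R0) {
  check_that(all(is.finite(R)) && all(R > 0), "R must be positive")
  check_that(is_number(R0) && R0 > 0, "R0 must be positive")
  1 / (1 + (R / R0)^6)
}

#' Homo-FRET distance-detection window
#'
#' Energy migration measurably changes the anisotropy decay only while
#' 0.8 < R/R0 < 1.7; outside the window the transfer rate is too fast or
#' too slow to resolve and a fitted distance is only a bound.
#'
#' @param R0 Forster radius, Angstroms.
#' @return named numeric `c(low, high)` = (0.8, 1.7) * R0.
#' @export
detection_range <- function(R0) {
  check_that(is_number(R0) && R0 > 0, "R0 must be positive")
  c(low = 0.8 * R0, high = 1.7 * R0)
}

#' @rdname detection_range
#' @param R distance(s) to test, Angstroms.
#' @return `in_detection_range`: logical, TRUE where R is inside the window.
#' @export
in_detection_range <- function(R, R0) {
  rng <- detection_range(R0)
  R > rng[["low"]] & R < rng[["high"]]
}
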