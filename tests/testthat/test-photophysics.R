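test_that("spectral center of mass: symmetry, delta case and quadrature oracle", {
  lam <- seq(300, 400, by = 2)
  flat <- emission_spectrum(lam, rep(1, length(lam)))
  expect_equal(spectral_center_of_mass(flat), 350)

  # trapezoidal weighting makes a single nonzero bin a pure delta
  delta <- rep(0, length(lam))
  delta[lam == 340] <- 7
  expect_equal(spectral_center_of_mass(emission_spectrum(lam, delta)), 340)

  # dense-grid numerical quadrature oracle for a Gaussian band
  g <- gaussian_spectrum(center = 345, sd = 20, by = 1)
  dense <- seq(300, 420, by = 0.001)
  I <- exp(-(dense - 345)^2 / (2 * 20^2))
  oracle <- sum(dense * I) / sum(I)
  expect_lt(abs(spectral_center_of_mass(g) - oracle), 0.5)

  expect_error(spectral_center_of_mass(
    emission_spectrum(lam, rep(0, length(lam)))), "zero total intensity")
})

test_that("center of mass is invariant to uniform intensity scaling", {
  g <- gaussian_spectrum()
  scaled <- emission_spectrum(g$wavelength_nm, g$intensity * 137.2)
  expect_equal(spectral_center_of_mass(scaled), spectral_center_of_mass(g))
})

test_that("relative quantum yield: identity, linear scaling, dilute warning", {
  g <- gaussian_spectrum()
  expect_equal(quantum_yield_relative(g, 0.05, g, 0.05, phi_ref = 0.14), 0.14)
  g2 <- emission_spectrum(g$wavelength_nm, 2 * g$intensity)
  expect_equal(quantum_yield_relative(g2, 0.05, g, 0.05, phi_ref = 0.14), 0.28)
  # area/absorbance combination landing mid-band of a tryptophan reporter
  expect_equal(
    quantum_yield_relative(g2, 0.05 * 2 * 0.14 / 0.285, g, 0.05, 0.14),
    0.285)
  expect_warning(quantum_yield_relative(g, 0.2, g, 0.05), "dilute")
  expect_warning(phi <- quantum_yield_relative(g2, 0.001, g, 0.05), "clipped")
  expect_equal(as.numeric(phi), 1)
  expect_gt(attr(phi, "raw"), 1)
  expect_error(quantum_yield_relative(g, 0, g, 0.05), "positive")
})

test_that("overlap integral: zero epsilon, factorization and closed-form oracle", {
  g <- gaussian_spectrum()
  zero_abs <- absorption_spectrum(g$wavelength_nm, rep(0, length(g$wavelength_nm)))
  expect_equal(spectral_overlap(g, zero_abs), 0)

  # constant epsilon factorizes: J = c * <lambda^4> under the normalized donor
  const_abs <- absorption_spectrum(g$wavelength_nm,
                                   rep(5000, length(g$wavelength_nm)))
  lam <- g$wavelength_nm
  area <- tetrafret:::trapz(lam, g$intensity)
  expected <- 5000 * tetrafret:::trapz(lam, g$intensity * lam^4) / area
  expect_equal(spectral_overlap(g, const_abs), expected, tolerance = 1e-12)

  # boxcar donor x boxcar acceptor on [330, 350]: closed-form polynomial
  lam_box <- seq(330, 350, by = 0.25)
  box_em <- emission_spectrum(lam_box, rep(1, length(lam_box)))
  box_abs <- absorption_spectrum(lam_box, rep(5000, length(lam_box)))
  oracle <- 5000 * (350^5 - 330^5) / 5 / 20   # 6.693241e13
  expect_equal(spectral_overlap(box_em, box_abs), oracle, tolerance = 1e-6)

  far <- absorption_spectrum(seq(500, 600, 10), rep(1, 11))
  expect_error(spectral_overlap(g, far), "overlap")
})

test_that("J is linear in epsilon and invariant to donor scaling", {
  g <- gaussian_spectrum()
  eps <- absorption_spectrum(g$wavelength_nm, 4000 + 10 * g$wavelength_nm)
  J1 <- spectral_overlap(g, eps)
  eps3 <- absorption_spectrum(eps$wavelength_nm, 3 * eps$epsilon)
  expect_equal(spectral_overlap(g, eps3), 3 * J1, tolerance = 1e-12)
  g_scaled <- emission_spectrum(g$wavelength_nm, 42 * g$intensity)
  expect_equal(spectral_overlap(g_scaled, eps), J1, tolerance = 1e-12)
})

test_that("Forster radius: scaling law, inverse identity, tryptophan band", {
  p <- forster_params(phi_d = 0.285, J = 2e12)
  p2 <- forster_params(phi_d = 0.57, J = 2e12)
  expect_equal(forster_radius(p2) / forster_radius(p), 2^(1/6),
               tolerance = 1e-12)

  # inverse-J solve round-trips to the target radius
  target <- 13
  J_inv <- (target / 0.2108)^6 / ((2/3) * 1.6^-4 * 0.285)
  p_inv <- forster_params(phi_d = 0.285, J = J_inv)
  expect_equal(forster_radius(p_inv), target, tolerance = 1e-9)

  # with the stated kappa2/n and QY in 0.27-0.3, J of order 2e12 puts R0 in
  # the 12-14 A band reported for this reporter
  for (phi in c(0.27, 0.285, 0.3)) {
    r0 <- forster_radius(forster_params(phi_d = phi, J = 2e12))
    expect_gt(r0, 12); expect_lt(r0, 14)
  }
  expect_error(forster_radius(forster_params(phi_d = 0.3, J = 0)),
               "undefined")
})

test_that("FRET efficiency: half point, limits, monotone decreasing", {
  expect_equal(fret_efficiency(13, 13), 0.5)
  expect_equal(fret_efficiency(1e-9, 13), 1, tolerance = 1e-6)
  expect_equal(fret_efficiency(26, 13), 1/65, tolerance = 1e-12)
  R <- seq(5, 40, by = 0.5)
  expect_true(all(diff(fret_efficiency(R, 13)) < 0))
  expect_error(fret_efficiency(-1, 13), "positive")
})

test_that("detection window scales with R0 and flags out-of-range distances", {
  expect_equal(unname(detection_range(10)), c(8, 17))
  # R0 band 12-14 A gives a union window of about 10-22 A
  lo <- detection_range(12)[["low"]]
  hi <- detection_range(14)[["high"]]
  expect_equal(lo, 9.6, tolerance = 0.05)
  expect_equal(hi, 23.8, tolerance = 0.05)
  expect_false(in_detection_range(25, 13))
  expect_true(in_detection_range(15, 13))
  # consistency between predicate and bounds
  expect_equal(in_detection_range(c(0.79, 0.81, 1.69, 1.71) * 13, 13),
               c(FALSE, TRUE, TRUE, FALSE))
})
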