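test_that("two-state melt model: midpoint, limits and frozen oracle value", {
  # at Tm the signal is the midpoint of the two baselines, any enthalpy
  for (dH in c(200, 400, 600)) {
    s <- two_state_melt_model(62, 62, dH, c(1, 0), c(0, 0))
    expect_equal(s, 0.5, tolerance = 1e-12)
  }
  expect_equal(two_state_melt_model(20, 62, 400, c(1, 0), c(0, 0)), 1,
               tolerance = 1e-6)
  expect_equal(two_state_melt_model(95, 62, 400, c(1, 0), c(0, 0)), 0,
               tolerance = 1e-4)
  # direct evaluation oracle (R = 8.314, T in K = degC + 273.15)
  expect_equal(two_state_melt_model(62, 60, 400, c(1, 0), c(0, 0)),
               0.2969657, tolerance = 1e-6)
  # unfolded fraction strictly increasing in temperature
  fU <- tetrafret:::unfolded_fraction(seq(30, 90, 0.5), 60, 400)
  expect_true(all(diff(fU) > 0))
})

test_that("melt fitting: exact on noiseless data, 0.3 degC recovery at 1% noise", {
  Tc <- seq(30, 90, by = 0.5)
  clean <- two_state_melt_model(Tc, 62, 400, c(1, -0.003), c(0.25, -0.001))
  f <- fit_melt(melt_curve(Tc, clean))
  expect_true(f$ok)
  expect_equal(f$tm_C, 62, tolerance = 1e-3)
  expect_equal(f$dH_vH, 400, tolerance = 1e-2)
  expect_equal(f$baseline_native, c(1, -0.003), tolerance = 1e-4)

  # reduced-seed noise recovery (full grid in the acceptance suite)
  errs <- vapply(1:5, function(s) {
    sig <- 0.01 * diff(range(clean))
    y <- tetrafret:::with_seed(derive_seed(s, "melt_test"),
                               clean + rnorm(length(clean), 0, sig))
    fit_melt(melt_curve(Tc, y))$tm_C - 62
  }, numeric(1))
  expect_lte(median(abs(errs)), 0.3)

  # flat curve -> flagged failure, not an exception
  flat <- melt_curve(Tc, rep(1, length(Tc)) +
                       tetrafret:::with_seed(1, rnorm(length(Tc), 0, 1e-3)))
  ff <- fit_melt(flat)
  expect_false(ff$ok)
  expect_true(ff$no_transition)

  # transition at the edge of the window is flagged
  edge <- two_state_melt_model(Tc, 88.5, 400, c(1, 0), c(0, 0))
  fe <- fit_melt(melt_curve(Tc, edge))
  expect_true(fe$ok && fe$edge_flag)
})

test_that("K+ melt series stabilizes dose-dependently; Na+ series stays flat", {
  conc <- c(0, 10^seq(-5, 0, length.out = 9))
  mk <- gen_melt_series("NaK2K_K", conc, noise_spec(seed = 2))
  tms <- vapply(mk, function(m) fit_melt(m)$tm_C, numeric(1))
  # monotone nondecreasing within noise
  expect_true(all(diff(tms) > -0.3))
  expect_gt(max(tms) - min(tms), 10)

  mna <- gen_melt_series("NaK2K_Na", conc, noise_spec(seed = 2))
  tmsna <- vapply(mna, function(m) fit_melt(m)$tm_C, numeric(1))
  # up to 1 M Na+: spread below 3x the per-fit noise scale
  expect_lt(max(tmsna) - min(tmsna), 3 * 0.2)
})

test_that("Hill fit: half-effect at kd for n=1, recovery, hyperbola reduction", {
  conc <- c(0, 10^seq(-5.5, -1.5, length.out = 11))
  kd <- 4e-4
  clean <- 352 - 2 * conc / (kd + conc)
  s <- titration_series(conc, clean, "lambda_com_nm")
  f <- suppressWarnings(hill_fit(s, n_hill = 1))
  expect_equal(f$kd_app_M, kd, tolerance = 1e-6)
  expect_equal(f$s0 + f$ds / 2, 352 - 2 * kd / (kd + kd), tolerance = 1e-6)

  # fitting hyperbolic truth with n free recovers n near 1
  ffree <- suppressWarnings(hill_fit(s))
  expect_equal(ffree$n_hill, 1, tolerance = 0.15)

  # blue-shift series with kd = 4e-4, n = 1.5: kd and n within 15% (median)
  p <- scenario_preset("NaK_K")
  p$hill$lambda_com_nm$kd_M <- 4e-4
  rel <- t(vapply(1:5, function(sd) {
    ts <- gen_titration(p, "lambda_com_nm", noise = noise_spec(seed = sd))
    ff <- suppressWarnings(hill_fit(ts))
    c(abs(ff$kd_app_M / 4e-4 - 1), abs(ff$n_hill / 1.5 - 1))
  }, numeric(2)))
  expect_lt(median(rel[, 1]), 0.15)
  expect_lt(median(rel[, 2]), 0.15)

  # saturation concentration lands in the 1-2 mM band for submillimolar kd
  ts <- gen_titration("NaK2K_K", "r_ss", noise = noise_spec(seed = 3))
  fsat <- suppressWarnings(hill_fit(ts))
  expect_gt(fsat$l95_M, 1e-3)
  expect_lt(fsat$l95_M, 5e-3)
})

test_that("Tm titration: kd recovery, submillimolar band, no-binding flag", {
  ts <- gen_titration("NaK2K_K", "tm_C",
                      conc_M = c(0, 10^seq(-5, -1, length.out = 11)),
                      noise = noise_spec(seed = 4))
  f <- suppressWarnings(fit_tm_titration(ts, n_hill = 1))
  expect_false(f$no_binding)
  expect_equal(f$kd_app_M, 3e-4, tolerance = 0.15)
  expect_lt(f$kd_app_M, 1e-3)   # submillimolar

  # flat Na+-type series: kd undefined, flagged
  tsna <- gen_titration("NaK2K_Na", "tm_C", noise = noise_spec(seed = 4))
  fna <- suppressWarnings(fit_tm_titration(tsna))
  expect_true(fna$no_binding)

  # narrow grid triggers the two-decade warning (plus a plateau warning)
  narrow <- titration_series(c(0, 1e-4, 2e-4, 3e-4, 4e-4),
                             c(60, 62, 64, 65, 65.5), "tm_C")
  w <- capture_warnings(fit_tm_titration(narrow))
  expect_match(w, "two decades", all = FALSE)
})

test_that("four-site presets give ~2x amplitudes of two-site presets", {
  for (obs in c("lambda_com_nm", "r_ss")) {
    f4 <- suppressWarnings(hill_fit(
      gen_titration("NaK2K_K", obs, noise = noise_spec(seed = 5))))
    f2 <- suppressWarnings(hill_fit(
      gen_titration("NaK_K", obs, noise = noise_spec(seed = 5))))
    expect_equal(abs(f4$ds) / abs(f2$ds), 2, tolerance = 0.25)
  }
})

test_that("single-binding-scheme report aggregates kd values and flags outliers", {
  mk <- function(kd) structure(list(ok = TRUE, no_binding = FALSE,
                                    kd_app_M = kd, observable = "x"),
                               class = "hill_fit")
  same <- single_binding_scheme_report(list(mk(3e-4), mk(3e-4)))
  expect_equal(same$spread_ratio, 1)
  expect_true(same$consistent)

  r <- single_binding_scheme_report(list(mk(3e-4), mk(4e-4), mk(5e-4)))
  expect_equal(r$kd_geomean_M, (3 * 4 * 5)^(1/3) * 1e-4, tolerance = 1e-9)
  expect_true(r$consistent)

  off <- single_binding_scheme_report(list(mk(3e-4), mk(4e-4), mk(3e-3)))
  expect_false(off$consistent)
  expect_match(off$flag, "disagree")
})
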