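test_that("generators are bitwise reproducible given a seed and independent across streams", {
  ns <- noise_spec(seed = 42)
  a <- gen_tcspc_pair("NaK_K", ns)
  b <- gen_tcspc_pair("NaK_K", ns)
  expect_identical(a$parallel$counts, b$parallel$counts)
  expect_identical(a$perpendicular$counts, b$perpendicular$counts)

  iv1 <- gen_iv("NaK2K_K", noise = ns)
  iv2 <- gen_iv("NaK2K_K", noise = ns)
  expect_identical(iv1$current_pA, iv2$current_pA)

  # different seeds differ; different generator names draw different streams
  c2 <- gen_tcspc_pair("NaK_K", noise_spec(seed = 43))
  expect_false(identical(a$parallel$counts, c2$parallel$counts))
  expect_false(derive_seed(42, "tcspc_NaK_K") == derive_seed(42, "iv_NaK_K"))

  # generators do not disturb the global RNG state
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_tcspc_pair("NaK_K", ns)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noiseless forward models round-trip through the fitters exactly", {
  pair <- gen_tcspc_pair("NaK2K_K", noise_spec(seed = 1), noiseless = TRUE)
  truth <- attr(pair, "truth")
  rtrace <- anisotropy_from_polarized(pair, intensity_floor = 0)
  model <- tetramer_anisotropy(pair$parallel$time_ns, truth$r0, truth$k1,
                               truth$phi_g_ns)
  expect_lt(max(abs(rtrace$counts - model)), 1e-12)

  mc <- gen_melt_series("NaK_K", 1e-3, noise_spec(seed = 1),
                        noiseless = TRUE)
  f <- fit_melt(mc[[1]])
  expect_equal(f$tm_C, attr(mc, "truth")$tm_C, tolerance = 1e-4)

  ts <- gen_titration("NaK2K_K", "lambda_com_nm", noise = noise_spec(seed = 1),
                      noiseless = TRUE)
  h <- suppressWarnings(hill_fit(ts))
  expect_equal(h$kd_app_M, 3e-4, tolerance = 1e-5)
  expect_equal(h$n_hill, 1.5, tolerance = 1e-5)

  iv <- gen_iv("NaK_K", noise = noise_spec(seed = 1), noiseless = TRUE)
  expect_equal(reversal_from_iv(iv), 0, tolerance = 1e-9)
})

test_that("per-bin Poisson statistics: replicate means stay inside 3-sigma bands", {
  # 200 seeded replicates of a short histogram, compared bin-wise to the
  # expected counts (law of large numbers check on a thinned bin subset)
  p <- scenario_preset("NaK_K")
  expect_mean <- gen_tcspc_pair(p, noise_spec(seed = 1), n_bins = 64,
                                noiseless = TRUE)$parallel$counts
  acc <- matrix(0, 200, 64)
  for (s in 1:200)
    acc[s, ] <- gen_tcspc_pair(p, noise_spec(seed = s),
                               n_bins = 64)$parallel$counts
  m <- colMeans(acc)
  se <- sqrt(expect_mean / 200)
  frac_in <- mean(abs(m - expect_mean) <= 3 * se)
  expect_gt(frac_in, 0.99)
})

test_that("preset distance ordering and binding structure are encoded", {
  r_nak2k_k <- scenario_preset("NaK2K_K")$decay$R_true_angstrom
  r_nak_k <- scenario_preset("NaK_K")$decay$R_true_angstrom
  r_na <- scenario_preset("NaK_Na")$decay$R_true_angstrom
  expect_true(r_nak2k_k < r_nak_k && r_nak_k < r_na)
  expect_equal(c(r_nak2k_k, r_nak_k, r_na), c(15, 18, 25))

  # K+ scenarios carry finite submillimolar kd; Na+ scenarios no Tm shift
  for (nm in c("NaK_K", "NaK2K_K")) {
    m <- scenario_preset(nm)$melt
    expect_lt(m$kd_M, 1e-3)
    expect_gt(m$dtm_C, 0)
  }
  for (nm in c("NaK_Na", "NaK2K_Na")) {
    m <- scenario_preset(nm)$melt
    expect_equal(m$dtm_C, 0)
  }
  # tryptophan-like lifetimes: <tau>2 within 4.5-5.1 ns for all presets
  for (nm in c("NaK_K", "NaK_Na", "NaK2K_K", "NaK2K_Na")) {
    d <- scenario_preset(nm)$decay
    t2 <- average_lifetimes(d$amplitudes, d$lifetimes)$tau2_int
    expect_gte(t2, 4.5); expect_lte(t2, 5.1)
  }
})

test_that("optional red-shift bump appears only above 10 mM and only when requested", {
  conc <- c(0, 10^seq(-5.5, -0.5, length.out = 13))
  plain <- gen_titration("NaK_K", "lambda_com_nm", conc,
                         noise_spec(seed = 1), noiseless = TRUE)
  bump <- gen_titration("NaK_K", "lambda_com_nm", conc,
                        noise_spec(seed = 1), include_red_shift = TRUE,
                        noiseless = TRUE)
  diffv <- bump$value - plain$value
  expect_true(all(diffv[conc <= 1e-3] < 0.02))
  expect_gt(max(diffv[conc > 1e-2]), 0.3)
})

test_that("CSV round trips preserve decays, melts, titrations and i/V data", {
  tmp <- withr::local_tempdir()
  pair <- gen_tcspc_pair("NaK_K", noise_spec(seed = 9), n_bins = 64)
  path <- file.path(tmp, "par.csv")
  write_decay_csv(pair$parallel, path)
  back <- read_decay_csv(path)
  expect_equal(back$channel, "parallel")
  expect_equal(back$counts, pair$parallel$counts)
  expect_equal(back$time_ns, pair$parallel$time_ns, tolerance = 1e-9)

  ivp <- file.path(tmp, "iv.csv")
  iv <- gen_iv("NaK2K_K", noise = noise_spec(seed = 9))
  utils::write.csv(data.frame(voltage_mV = iv$voltage_mV,
                              current_pA = iv$current_pA),
                   ivp, row.names = FALSE)
  expect_equal(read_iv_csv(ivp)$current_pA, iv$current_pA, tolerance = 1e-9)

  mp <- file.path(tmp, "melt.csv")
  m <- gen_melt_series("NaK_K", 1e-3, noise_spec(seed = 9))[[1]]
  utils::write.csv(data.frame(temperature_C = m$temperature_C,
                              signal = m$signal), mp, row.names = FALSE)
  expect_equal(read_melt_csv(mp, 1e-3)$signal, m$signal, tolerance = 1e-9)
})
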