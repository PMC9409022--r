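test_that("anisotropy from polarized: zero, fully polarized, model round trip", {
  t <- (0:127) * 0.1
  base <- 1000 * exp(-t / 5) + 10
  pair <- polarized_decay_pair(decay_histogram(t, base, "parallel"),
                               decay_histogram(t, base, "perpendicular"))
  r <- anisotropy_from_polarized(pair, intensity_floor = 0)
  expect_true(all(abs(r$counts) < 1e-12))

  pair1 <- polarized_decay_pair(decay_histogram(t, base, "parallel"),
                                decay_histogram(t, 0 * base, "perpendicular"))
  r1 <- anisotropy_from_polarized(pair1, intensity_floor = 0)
  expect_true(all(abs(r1$counts - 1) < 1e-12))

  # forward model round trip recovers r(t) to machine precision
  mp <- model_pair(r0 = 0.3, k1 = 0.1, phi_g = 40, lifetimes = 5)
  rtrace <- anisotropy_from_polarized(mp, intensity_floor = 0)
  truth <- tetramer_anisotropy(mp$parallel$time_ns, 0.3, 0.1, 40)
  expect_lt(max(abs(rtrace$counts - truth)), 1e-12)

  bad <- decay_histogram(t + 1, base, "perpendicular")
  expect_error(polarized_decay_pair(pair$parallel, bad), "identical")
})

test_that("total intensity histogram carries the two-channel Poisson variance", {
  mp <- gen_tcspc_pair("NaK2K_K", noise_spec(seed = 5))
  tot <- total_intensity_histogram(mp)
  expect_equal(tot$counts,
               mp$parallel$counts + 2 * mp$perpendicular$counts)
  v <- attr(tot, "variance")
  expect_true(all(v >= pmax(tot$counts * 0, 1)))
  expect_equal(v, pmax(mp$parallel$counts + 4 * mp$perpendicular$counts, 1))
})

test_that("intensity decay fitting: exact on noiseless, recovers under Poisson noise", {
  t <- (0:511) * 0.05
  clean <- decay_histogram(t, 2e4 * exp(-t / 5), "magic_angle")
  f1 <- fit_intensity_decay(clean, n_components = 1)
  expect_true(f1$ok)
  expect_equal(f1$lifetimes, 5, tolerance = 1e-6)
  expect_lt(f1$chi2r, 1e-10)

  # Poisson noise at 2e4 peak: tau within 2%, accepted fit
  taus <- vapply(1:5, function(s) {
    y <- tetrafret:::with_seed(derive_seed(s, "single_exp"),
                               rpois(length(t), 2e4 * exp(-t / 5)))
    f <- fit_intensity_decay(decay_histogram(t, y, "magic_angle"), 1)
    expect_lt(f$chi2r, 1.2)
    f$lifetimes
  }, numeric(1))
  expect_true(all(abs(taus - 5) / 5 < 0.02))

  # two-component tryptophan-like synthetics keep <tau>2 in the 4.5-5.1 ns
  # band when generated there
  for (s in 1:3) {
    pair <- gen_tcspc_pair("NaK_K", noise_spec(seed = s))
    f <- fit_intensity_decay(total_intensity_histogram(pair), 2)
    expect_true(f$ok)
    expect_gt(f$tau2_int, 4.5)
    expect_lt(f$tau2_int, 5.1)
  }
})

test_that("anisotropy decay fitting: exact on noiseless traces, k1 within 5% under noise", {
  # noiseless model trace supplied directly as an anisotropy histogram
  t <- (0:1023) * 0.05
  trace <- decay_histogram(t, tetramer_anisotropy(t, 0.3, 0.0848, 40),
                           "anisotropy")
  f <- fit_anisotropy_decay(trace, phi_g = 40)
  expect_equal(f$r0, 0.3, tolerance = 1e-6)
  expect_equal(f$k1, 0.0848, tolerance = 1e-5)

  # Poisson-noise polarised pairs at 2e4 peak
  rel <- vapply(1:5, function(s) {
    p <- distance_preset(15)
    pair <- gen_tcspc_pair(p, noise_spec(seed = s))
    k1_true <- attr(pair, "truth")$k1
    fit <- fit_anisotropy_decay(pair, phi_g = 40)
    abs(fit$k1 - k1_true) / k1_true
  }, numeric(1))
  expect_lt(median(rel), 0.05)

  # fixed-r0 mode
  pair <- gen_tcspc_pair(distance_preset(15), noise_spec(seed = 1))
  ffix <- fit_anisotropy_decay(pair, phi_g = 40, r0 = 0.3)
  expect_true(ffix$r0_fixed)
  expect_equal(ffix$r0, 0.3)
  expect_equal(ffix$k1, attr(pair, "truth")$k1, tolerance = 0.05)
})

test_that("K+-like presets depolarize faster than Na+-like presets", {
  fk <- fit_anisotropy_decay(gen_tcspc_pair("NaK2K_K", noise_spec(seed = 3)),
                             phi_g = 40)
  fna <- fit_anisotropy_decay(gen_tcspc_pair("NaK2K_Na", noise_spec(seed = 3)),
                              phi_g = 40)
  expect_gt(fk$k1, fna$k1)
  fk2 <- fit_anisotropy_decay(gen_tcspc_pair("NaK_K", noise_spec(seed = 3)),
                              phi_g = 40)
  fna2 <- fit_anisotropy_decay(gen_tcspc_pair("NaK_Na", noise_spec(seed = 3)),
                               phi_g = 40)
  expect_gt(fk2$k1, fna2$k1)
})

test_that("rotational correlation time recovered from the pyrene probe", {
  # noiseless single-term decay is recovered exactly
  t <- (0:511) * 0.25
  trace <- decay_histogram(t, 0.3 * exp(-t / 40), "anisotropy")
  f1 <- fit_rotational_correlation(trace, n_terms = 1)
  expect_equal(f1$phi_g, 40, tolerance = 1e-6)

  # fast wobble + tumbling: long component within 40 +/- 2
  clean <- gen_pyrene_pair(noise_spec(seed = 1), noiseless = TRUE)
  fc <- fit_rotational_correlation(clean)
  expect_equal(fc$phi_g, 40, tolerance = 0.05)

  ests <- vapply(1:5, function(s)
    fit_rotational_correlation(gen_pyrene_pair(noise_spec(seed = s)))$phi_g,
    numeric(1))
  expect_lt(median(abs(ests - 40)), 2)
  # estimates within the printed 37-43 ns uncertainty band
  expect_true(all(ests > 37 & ests < 43))
})

test_that("full-chain distance recovery and lower-bound flagging (reduced seeds)", {
  for (Rt in c(15, 18)) {
    errs <- vapply(1:5, function(s)
      recover_distance(distance_preset(Rt), s)$R - Rt, numeric(1))
    expect_lte(median(abs(errs)), 1)
  }
  g25 <- recover_distance(distance_preset(25), 1)
  expect_true(g25$lower_bound_flag)
})
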