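# Shared fixture builders and independent oracles for the test suite.

# Gaussian-shaped emission spectrum on a wavelength grid.
gaussian_spectrum <- function(center = 345, sd = 20, from = 300, to = 420,
                              by = 1) {
  lam <- seq(from, to, by = by)
  emission_spectrum(lam, exp(-(lam - center)^2 / (2 * sd^2)))
}

# Noiseless polarised pair built directly from model parameters (forward
# model identical in structure to the generator, but assembled here so
# round-trip tests do not depend on gen_tcspc_pair internals).
model_pair <- function(r0 = 0.3, k1 = 0.1, phi_g = 40, amplitudes = 1,
                       lifetimes = 5, n_bins = 1024, dt = 0.05,
                       peak = 2e4) {
  t <- (seq_len(n_bins) - 1) * dt
  I <- multiexp_intensity(t, amplitudes, lifetimes)
  r <- tetramer_anisotropy(t, r0, k1, phi_g)
  epar <- I * (1 + 2 * r) / 3
  eperp <- I * (1 - r) / 3
  sc <- peak / max(epar)
  polarized_decay_pair(decay_histogram(t, epar * sc, "parallel"),
                       decay_histogram(t, eperp * sc, "perpendicular"))
}

# Preset with a custom true distance but the reference decay parameters
# (tau components 3/6 ns so <tau>2 = 5 ns exactly, r0 = 0.3, R0 = 13 A).
distance_preset <- function(R_true) {
  p <- scenario_preset("NaK2K_K")
  p$decay$R_true_angstrom <- R_true
  p
}

# Full spectroscopic-ruler chain on one simulated pair: lifetimes from the
# total-intensity decay, k1 from the anisotropy decay, distance from the
# sixth-power law.
recover_distance <- function(preset, seed, phi_g = 40) {
  pair <- gen_tcspc_pair(preset, noise_spec(seed = seed))
  ifit <- fit_intensity_decay(total_intensity_histogram(pair), 2)
  afit <- fit_anisotropy_decay(pair, phi_g = phi_g)
  distance_from_k1(afit$k1, preset$decay$R0_angstrom, ifit$tau2_int)
}
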