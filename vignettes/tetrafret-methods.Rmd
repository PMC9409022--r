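---
title: "Methods: the homo-FRET ruler, binding and selectivity models in tetrafret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the homo-FRET ruler, binding and selectivity models in tetrafret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrafret)
```

# The system and the measurement

A tetrameric cation channel with one tryptophan reporter per subunit places
four chemically identical fluorophores at the corners of a square around
the pore. Excitation energy migrates reversibly between them by homo-FRET;
migration does not change the fluorescence lifetime but depolarises the
emission, so the *anisotropy* decay carries the migration rate, and through
it the side length of the reporter square. `tetrafret` implements this
spectroscopic ruler together with the two companion analyses that give it
biological meaning: ligand-binding isotherms (thermal shifts and
spectroscopic titrations) and bi-ionic permeability ratios.

# The anisotropy model

## Energy migration on a square

For a square tetramer the anisotropy decay is

$$r(t) = \frac{r_0}{4}\left[1 + e^{-4k_1t} + 2e^{-\frac94 k_1t}\right]
e^{-t/\phi_g},$$

the product of the probability that the excitation still resides on the
directly excited corner and the overall tumbling of the protein–detergent
complex. The model rests on four assumptions: (i) migration is pure
homo-FRET and fully reversible (all four fluorophores are spectroscopically
equivalent); (ii) transfer is isotropic; (iii) indirectly excited
fluorophores emit unpolarised light, so only the directly excited corner
contributes to $r(t)$; (iv) tumbling is isotropic with a single long
correlation time $\phi_g$.

The bracket is the $p_{11}(t)$ element of the 4-state master equation on a
square with nearest-neighbour rate $k_1$ (two neighbours per corner) and
diagonal rate $k_2$. The package fixes $k_2 = k_1/8$: the diagonal is
$\sqrt2$ times the side, and the $R^{-6}$ law gives $(\sqrt2)^{-6} = 1/8$.
This choice is not free — the $9/4$ coefficient in the closed form is
algebraically consistent *only* with $k_2 = k_1/8$ (the eigenvalues of the
rate matrix are $0$, $-4k_1$ and twice $-2(k_1+k_2)$). The test suite
verifies the closed form against `master_equation_oracle()`, an independent
eigen-decomposition of the rate matrix, to $10^{-10}$ over random
$(k_1, t)$ pairs, and verifies that violating $k_2 = k_1/8$ breaks the
agreement.

## From rate to distance

$k_1 = \tau^{-1}(R_0/R)^6$, with $\tau$ the *intensity-weighted* mean
lifetime $\langle\tau\rangle_2 = \sum\alpha_i\tau_i^2/\sum\alpha_i\tau_i$
of the same sample — the amplitude-weighted mean would underweight the
photons that actually carry the depolarisation information. Distances are
meaningful only inside the detection window $0.8 < R/R_0 < 1.7$: below it
migration is complete within the instrument response, above it too little
transfer occurs to measure. `distance_from_k1()` therefore flags any
$R > 1.7R_0$ as a lower bound, and reports $k_1 = 0$ as "beyond detection"
rather than a number. With $R_0 \approx 13$ Å the window is roughly
10–22 Å, which is why a 25 Å wide-open pore is reported as "at least
~25 Å", systematically underestimated — a behaviour the acceptance suite
reproduces on synthetic data.

## Fitting choices

* **Variable projection.** Every model in the package is linear in its
  amplitudes (decay amplitudes, $r_0$, baselines, Hill endpoints) given its
  few nonlinear parameters (lifetimes, $k_1$, $t_m$, $\Delta H$, $K_D$,
  $n$). The fitter solves the linear subproblem exactly per candidate via
  weighted least squares and optimises only the nonlinear parameters
  (L-BFGS-B, box-bounded), from 5 deterministic log-spaced starts. Ties are
  broken by lowest reduced $\chi^2$, then lowest first parameter. This is
  markedly more robust than optimising all parameters jointly and makes
  multi-start behaviour reproducible.
* **Weights.** TCSPC histograms get Poisson weights $1/\max(y, 1)$. The
  total-intensity decay reconstructed as $I_\parallel + 2GI_\perp$ is a sum
  of two Poisson channels, so its variance is $I_\parallel + 4G^2I_\perp$,
  which `total_intensity_histogram()` attaches and the fitter honours —
  using $1/S$ there would inflate $\chi^2_r$ by ~50% and wrongly reject
  correct fits. Anisotropy traces are weighted by per-bin errors propagated
  from the counting statistics of both channels, and bins with total
  intensity below a floor (default 50 counts) are masked.
* **Acceptance rule.** A decay fit is accepted when $\chi^2_r < 1.2$ *and*
  a Wald–Wolfowitz runs test finds the weighted residuals sign-random at
  the 5% level. Non-convergence is a flagged result, never an exception, so
  pipeline branches continue independently.
* **IRF.** The default is a delta-function response: tail-fitting from the
  peak bin onward. This is the verifiable baseline; an optional Gaussian
  IRF with discrete reconvolution (`irf = list(fwhm_ns =, t0_ns =)`) is
  provided for data where the rise matters. Measured-lamp deconvolution is
  out of scope.
* **$r_0$ and $\phi_g$.** $r_0$ is fitted by default (bounded by the 0.4
  theoretical tryptophan maximum, values above it flagged) with an option
  to fix it at the fundamental value ~0.3; fits in practice float it.
  $\phi_g$ is *always* held fixed — it is measured independently from a
  pyrene conjugate whose ~50 ns lifetime actually samples the ~40 ns
  tumbling ([fit_rotational_correlation()] fits a 1–2 term exponential
  anisotropy and returns the dominant long time). Floating $\phi_g$
  together with $k_1$ on a ~5 ns tryptophan decay would be poorly
  identifiable.
* **Grids.** Time axes are uniform, half-open, default 1024 bins of
  0.05 ns. Seeds are explicit arguments everywhere; no global RNG state is
  used or perturbed.

# Binding analyses

Melt curves are fitted with a two-state van't Hoff equilibrium,
$K(T) = \exp[-\Delta H_{vH}(1 - T/T_m)/RT]$, with linear pre- and
post-transition baselines; $t_m$ and $\Delta H$ are the nonlinear
parameters, the four baseline coefficients are projected out. $\Delta C_p$
is fixed at zero: it is not identifiable from a single-wavelength melt.
Temperatures are Celsius at the interface and Kelvin internally
($R = 8.314$ J mol⁻¹ K⁻¹). A fitted $t_m$ within 2 °C of either data edge
is flagged; a curve whose smoothed span does not exceed 5× the noise floor
is reported as "no transition", not fitted.

Ligand dependences are fitted with the empiric Hill isotherm
$S([L]) = s_0 + \Delta s\,[L]^n/(K_D^n + [L]^n)$, in *linear*
concentration so the zero-concentration anchor poses no problem, with
$K_D$ and $n$ optimised on log scale. We deliberately use the occupancy
form for the $t_m$ shift rather than a thermodynamic Schellman linkage
model: the linkage model is unidentifiable without $\Delta C_p$ and
calorimetric data, and the resulting constants are reported as *apparent*.
The fit also reports the 95% saturation concentration
$[L]_{95} = K_D\,19^{1/n}$, which for submillimolar $K_D$ lands in the
1–2 mM band where the titrations visibly saturate. The `no_binding` flag
is raised when the realised amplitude $|\Delta s|$ is below 5× the
residual noise — this is what a 1 M Na⁺ titration of these channels looks
like. An optional concentration cutoff excludes the small >10 mM red-shift
of the two-site channel's emission (a hydration effect, not binding) from
the fit; the default applies no cutoff. `single_binding_scheme_report()`
aggregates the per-observable $K_D$s and flags disagreement beyond 3×,
the internal consistency check for the single-binding-event scheme.

# Electrophysiology

Only the two monovalent cations enter the bi-ionic GHK form, as printed;
anions and substitute cations are excluded, concentrations are used as-is
(no activity coefficients), and i/V inputs are assumed junction-corrected
upstream. The inversion
$x = ([K]_o - e^{FE/RT}[K]_i)/(e^{FE/RT}[Na]_i - [Na]_o)$ is closed-form
and round-trips with the forward relation to $10^{-12}$. Note the known
discrepancy documented with the package: direct inversion at the printed
mean reversal of +18.6 mV gives $x = 0.426$, while per-patch inversion
followed by averaging gives 0.45 ± 0.01; both are exposed, the difference
is not resolved here. Reversal potentials are extracted from i/V series by
linear interpolation between the bracketing points (optionally a local
regression), slope conductances by least squares per voltage branch
(pA/mV × 1000 = pS), and ACMA flux traces are normalised to the
CCCP/valinomycin span.

# The synthetic-data generators

The generators emulate, with explicit seeds: Poisson-distributed polarised
TCSPC pairs built from the exact forward model
($I_\parallel \propto I(1+2r)/3$, $I_\perp \propto I(1-r)/3$, peak
2×10⁴ counts); two-state melt curves whose $t_m$ follows the preset
occupancy law; Hill-shaped titrations with signed amplitudes; blended
piecewise-linear i/V series; and exponential flux quenches. Presets encode
the stated world: tryptophan-like lifetimes with
$\langle\tau\rangle_2$ in 4.5–5.1 ns, $r_0 = 0.3$, $\phi_g = 40$ ns,
$R_0 = 13$ Å, true distances 15 / 18 / 25 Å, submillimolar $K_D$s
(3×10⁻⁴ and 5×10⁻⁴ M), two-fold NaK2K amplitudes, and reversal potentials
of 0 / +18.6 mV. Values the source material leaves open were fixed once at
field-typical levels and not revisited: $\Delta H_{vH}$ 350–400 kJ/mol
(melts of a ~100 kDa tetramer), titration noise 0.2 °C / 0.1 nm / 0.002 /
0.3 Å per observable, i/V noise 0.05 pA on seal-averaged points, melt
noise 1% of amplitude.

One deliberate deviation from a naive generator: the i/V series blends the
two branch conductances logistically (width 25 mV) around $E_{rev}$
instead of a hard kink. A kink exactly at the reversal biases linear
interpolation by about +1 mV at 10 mV steps, which would defeat the
recovery behaviour the extraction is supposed to have on this data; the
blend leaves the branch conductances intact far from the reversal.

Each generator call derives its own RNG stream from
`derive_seed(seed, generator_name)`, so fixtures never share randomness,
and restores the global RNG state afterwards — generation is bitwise
reproducible and side-effect free.

**What a green test establishes.** The generators produce exactly the
statistical structure the fitters assume (Poisson counting noise, Gaussian
observable noise, the exact forward models). Recovery tests therefore
establish correctness and calibration of the estimation chain — not
robustness to instrument artefacts the generators do not model: detector
afterpulsing, real lamp IRFs, associated anisotropies, baseline drifts,
liposome heterogeneity or junction-potential errors. Flags and acceptance
rules are exercised on data where their ground truth is known by
construction.

# Pipeline and configuration

`run_pipeline()` executes decay → lifetimes → $k_1$ → distance, melts →
$t_m$ → $K_D$, titrations → Hill → consistency, and i/V → reversal →
permeability, from a single config with a seed; independent branches
continue past flagged failures, and re-running an identical config
byte-reproduces the numeric payload. Configs are JSON (the spec of this
package allows YAML as an alternative; no YAML parser is available in the
supported dependency set, so JSON is the single config format). Reports
are JSON plus a human-readable summary.

# Known limitations

* End-to-end file-input mode is not wired into `run_pipeline()`; file
  inputs are analysed stage-by-stage through the `read_*` + `fit_*`
  functions or the CLI verbs. Scenario mode covers the full chain.
* No global/linked analysis across datasets; each decay, melt and
  titration is fitted independently.
* Wobble-in-cone models for the reporter itself, associated anisotropy,
  and measured-IRF deconvolution are out of scope.
* Asymptotic standard errors come from a finite-difference Jacobian at the
  optimum; for strongly correlated parameters (e.g. $K_D$ and $n$ on
  sparse grids) they understate the true uncertainty, and the
  `wide_ci_flag` / plateau warnings are the honest signal.
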