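# tetrafret

Quantitative analysis of pore conformational flexibility, K⁺ binding and
ion selectivity in tetrameric cation channels carrying a single tryptophan
reporter per subunit (e.g. Y55W mutants of NaK-type channels solubilised in
detergent micelles).

Because the four reporters sit at the corners of a square around the pore,
excitation energy migrates reversibly between them (homo-FRET), and the
rate of that migration is a spectroscopic ruler for the intersubunit
distance. `tetrafret` turns raw time-resolved anisotropy decays, thermal
melts, titrations and patch-clamp i/V series into distances, binding
constants and permeability ratios — and ships seeded synthetic-data
generators so the whole chain is testable without instrument data.

## The models

**Homo-FRET ruler.** The anisotropy decay of a square homotetramer with
lateral (nearest-neighbour) transfer rate $k_1$, diagonal rate $k_1/8$
(the $(\sqrt2)^{-6}$ distance law) and overall tumbling time $\phi_g$ is

$$r(t) = \frac{r_0}{4}\left[1 + e^{-4k_1t} + 2e^{-\frac{9}{4}k_1t}\right]
e^{-t/\phi_g}.$$

$\phi_g \approx 40$ ns is measured independently with a long-lifetime
pyrene probe and held fixed; $r_0$ and $k_1$ are fitted. The distance
follows from the sixth-power law $k_1 = \tau^{-1}(R_0/R)^6$, with $\tau$
the intensity-weighted mean fluorescence lifetime and $R_0$ the Förster
radius ($R_0 = 0.2108[\kappa^2 n^{-4}\Phi_D J]^{1/6}$ Å). Distances are
trustworthy only inside the window $0.8 < R/R_0 < 1.7$; beyond it the fit
reports a lower bound. The closed-form bracket is validated in the test
suite against a brute-force master equation on the 4-site square.

**Binding.** Melt curves are fitted with a two-state van't Hoff model with
sloping linear baselines; the ligand dependence of the midpoint $t_m$, and
of the spectroscopic observables (emission centre of mass, steady-state
anisotropy, distance), is fitted with an empiric Hill isotherm
$S([L]) = s_0 + \Delta s\,[L]^n/(K_D^n + [L]^n)$ giving apparent,
submillimolar-range $K_D$ values. Flat (Na⁺-type) series are flagged "no
binding detected".

**Selectivity.** Bi-ionic reversal potentials invert the two-ion
Goldman–Hodgkin–Katz relation

$$E_{rev} = \frac{RT}{F}\ln\frac{[K]_o + x[Na]_o}{[K]_i + x[Na]_i},
\qquad x = P_{Na}/P_K .$$

## Worked example

```r
library(tetrafret)

# simulate a four-site channel in K+ and run the full pipeline
report <- run_pipeline(list(scenario = "NaK2K_K", seed = 1))
report
#> tetrafret run report (scenario NaK2K_K, seed 1)
#>   R = 15.05 A
#>   Tm-shift kd_app = 0.000302 M
#>   Erev = 19.19 mV, P_Na/P_K = 0.414
```

The simulated truth is R = 15 Å, K_D = 3×10⁻⁴ M, E_rev = +18.6 mV: the
pipeline recovers the intersubunit distance to 0.05 Å, a submillimolar
binding constant, and a Na⁺/K⁺ permeability ratio near the 0.43 implied by
the reversal potential. Step by step:

```r
pair <- gen_tcspc_pair("NaK2K_K", noise_spec(seed = 1))
fit_intensity_decay(total_intensity_histogram(pair), n_components = 2)
#> 2-exponential intensity decay fit
#>   tau1 = 2.860 ns (alpha = 1.73e+04)
#>   tau2 = 5.860 ns (alpha = 2.03e+04)
#>   <tau>1 = 4.483 ns, <tau>2 = 4.982 ns
#>   chi2r = 1.118, runs z = -0.56 -> accepted

afit <- fit_anisotropy_decay(pair, phi_g = 40)
afit
#> Tetramer homo-FRET anisotropy fit (phi_g fixed at 40.0 ns)
#>   r0 = 0.2988, k1 = 0.08333 ns^-1, chi2r = 0.982

distance_from_k1(afit$k1, R0 = 13, tau = 4.98)
#> Lateral W-W distance R = 15.05 A (diagonal 21.29 A)
#>   from k1 = 0.08333 ns^-1, R0 = 13.0 A, tau = 4.98 ns

permeability_ratio_from_erev(18.6)   # bi-ionic default condition, 297 K
#> [1] 0.4260673
```

A reduced χ² below 1.2 with random residuals is the acceptance rule for
decay fits; `r0` close to the tryptophan fundamental anisotropy (~0.3)
confirms the fit is physical; `k1` converts to the lateral corner-to-corner
distance of the reporter square.

## Command line

```sh
Rscript inst/cli/tetrafret.R simulate --scenario NaK2K_K --out fixtures --seed 5
Rscript inst/cli/tetrafret.R fit-anisotropy --parallel fixtures/decay_parallel.csv \
        --perpendicular fixtures/decay_perpendicular.csv --phi-g 40
Rscript inst/cli/tetrafret.R ghk --erev 18.6
Rscript inst/cli/tetrafret.R run --config config.json
```

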