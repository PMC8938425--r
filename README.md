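# hairpinES

Design and exchange analysis of hairpin RNA excited states.

Small hairpin RNAs can be engineered so that a predefined low-populated
"excited" secondary structure (ES) exchanges with the ground state (GS)
through a base-pair register shift — the 3′ strand sliding by one or two
nucleotides against the 5′ strand — on the microsecond–millisecond
timescale. Such states are invisible to most structural methods but leave
clear fingerprints in NMR relaxation-dispersion (RD) experiments.
`hairpinES` implements the computational workflow around these systems,
for NMR spectroscopists and RNA designers:

- **Two-site exchange models.** The closed-form Laguerre approximation of
  the rotating-frame relaxation rate,

  R<sub>1ρ</sub> = R₁cos²θ + R₂sin²θ +
  sin²θ·p<sub>GS</sub>p<sub>ES</sub>Δω²k<sub>ex</sub> /
  [ω²<sub>GS</sub>ω²<sub>ES</sub>/ω²<sub>eff</sub> + k²<sub>ex</sub> −
  sin²θ·p<sub>GS</sub>p<sub>ES</sub>Δω²(1 +
  2k²<sub>ex</sub>(p<sub>GS</sub>ω²<sub>GS</sub> +
  p<sub>ES</sub>ω²<sub>ES</sub>) / (ω²<sub>GS</sub>ω²<sub>ES</sub> +
  ω²<sub>eff</sub>k²<sub>ex</sub>))],

  plus a full 6-dimensional Bloch–McConnell propagator used as its
  numerical oracle and as the CEST forward model
  (`laguerre_r1rho()`, `bm_evolve_r1rho()`, `simulate_cest()`).
- **Dispersion fitting.** Mono-exponential decay reduction with
  Monte Carlo errors, per-residue and global two-state fits sharing
  (p<sub>ES</sub>, k<sub>ex</sub>), CEST
  normalization/difference/fitting with frozen exchange parameters, and
  ES chemical-shift reconstruction (ES = GS + Δω).
- **Transition-state thermodynamics.** Eyring conversions and the
  modified van't Hoff fit ln(k/T) = ln(k<sub>B</sub>κ/h) −
  ΔG‡(T<sub>hm</sub>)/RT<sub>hm</sub> − (ΔH‡/R)(1/T − 1/T<sub>hm</sub>)
  at the harmonic-mean temperature.
- **Multi-step kinetics.** Rate matrices of linear free-energy chains
  (GS → I1…I4 → ES), spectral reduction to apparent two-state kinetics,
  uniform barrier tuning to a target apparent ΔG‡, the accumulated
  barrier of a hypothetical concerted transition, and a Gillespie
  first-passage oracle.
- **ES design.** Exhaustive 5-bp stem enumeration under the strong/weak
  pair rules (strong: Watson–Crick + G·U wobbles; weak: G·G, U·U, G·A,
  A·G), base-pair-triplet uniqueness, register-shift construction of the
  ES pairing, and the ΔΔG ≤ 3 kcal/mol design gate with an
  alternative-structure rank condition.
- **Synthetic data.** Seeded generators for R1ρ, CEST and
  multi-temperature rate datasets with known ground truth.

## Worked example

Exchange algebra for a construct whose global fit gave
k₁ = 28.1 s⁻¹ and k<sub>ex</sub> = 453 s⁻¹:

```r
library(hairpinES)
exchange_algebra(kex = 453, k1 = 28.1)
#> Two-state exchange: pES = 6.2% | kex = 453 s^-1 | k1 = 28.1 s^-1 | k-1 = 424.9 s^-1
#>   lifetimes: tau(GS) = 35.6 ms, tau(ES) = 2.35 ms
```

The minor state is populated at 6.2% and lives for 2.35 ms. A full
synthetic round trip — generate noisy dispersion data from a known truth
(p<sub>ES</sub> = 6.2%, k<sub>ex</sub> = 453 s⁻¹, four ¹⁵N probes with
Δω = 1.0–2.5 ppm, 2% intensity noise), reduce the decays, fit globally
and estimate Monte Carlo errors:

```r
ds  <- gen_r1rho_dataset(t1_truth(), seed = 7)
tbl <- r1rho_from_decays(ds$data, n_mc = 50, seed = 8)
fit <- mc_errors(fit_r1rho_global(tbl), n_mc = 50, seed = 9)
fit
#> Global two-state dispersion fit
#> Two-state exchange: pES = 5.8% | kex = 524.3 s^-1 | k1 = 30.41 s^-1 | k-1 = 493.9 s^-1
#>   lifetimes: tau(GS) = 32.9 ms, tau(ES) = 2.02 ms
#>   chi2/dof = 175 / 166  [MC errors from 50 iterations]
#>   residue nucleus larmor_MHz delta_omega delta_omega_ppm    R1    R2 dw_ppm_sd
#> 1      11      N1      60.82       403.9           1.057 2.002 17.72   0.04276
#> 2      14      N1      60.82       580.2           1.518 1.888 17.89   0.03171
#> 3      21      N3      60.82       780.7           2.043 1.973 17.72   0.04186
#> 4      23      N3      60.82       968.6           2.535 2.214 17.52   0.04864
```

The recovered populations sit a few tenths of a point below the truth —
the documented cost of fitting the closed-form approximation to exact
Bloch–McConnell data (see the methods vignette). Multi-step kinetics of
the six-state register-shift pathway, with barriers tuned so the
apparent two-state activation energy matches the measured
14.74 kcal/mol:

```r
tuned <- tune_barriers(six_state_chain(), 14.74)
app   <- apparent_two_state(build_rate_matrix(tuned))
#> largest barrier: 13.97 | apparent dG: 14.74 | concerted: 58.24  (kcal/mol)
```

Breaking the transition into five sequential single-base-pair steps
keeps the apparent barrier only ~0.8 kcal/mol above the largest single
step, while a concerted transition would have to pay ~58 kcal/mol at
once. Finally, the combinatorial designer:

```r
lib <- enumerate_stems(hairpin_spec(stem_len = 5))
#> Stem library (type1, stem_len = 5): 7776 strong-pair stems -> 7680 with
#> unique triplets -> 1072 with admissible ES
design_filter(lib)
#> Design filter: 32/1072 candidates accepted at ddG <= 3 kcal/mol
#>   best: GC GU GC GU AU  ddG = 0.43 kcal/mol
```

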