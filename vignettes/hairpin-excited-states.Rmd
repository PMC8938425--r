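---
title: "Models and methods: hairpin RNA excited states by relaxation dispersion"
author: "hairpinES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: hairpin RNA excited states by relaxation dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairpinES)
```

## The system and the model

A hairpin RNA built from a stable tetraloop on a variable stem can be
designed so that an alternative pairing — every 3′-strand base re-paired
with the 5′-strand partner one (or two) steps closer to the loop — lies
only a few kcal/mol above the ground state (GS). The molecule then
spends a small fraction of its time (0.5–10%) in this excited state
(ES), exchanging with the GS at hundreds to thousands of s⁻¹. Two NMR
observables report on that exchange: the rotating-frame relaxation rate
R1ρ of imino ¹⁵N nuclei as a function of spin-lock power and carrier
offset, and the saturation-transfer (CEST) profile of imino ¹H nuclei as
a weak B1 field is stepped across the spectrum.

Throughout, the exchange is two-state: populations $p_{GS} + p_{ES} =
1$, forward and backward rate constants $k_1 = p_{ES}k_{ex}$ and
$k_{-1} = p_{GS}k_{ex}$ with $k_{ex} = k_1 + k_{-1}$, and a
chemical-shift difference $\Delta\omega = \Omega_{ES} - \Omega_{GS}$ per
nucleus. `exchange_params()` stores this state and enforces the algebra
to 1e-9 relative; any sufficient pair of parameters may be supplied and
over-specified inputs are cross-checked rather than silently trusted.

### Closed-form R1ρ

`laguerre_r1rho()` implements the second-order Laguerre approximation

$$R_{1\rho} = R_1\cos^2\theta + R_2\sin^2\theta +
\frac{\sin^2\theta\, p_{GS}p_{ES}\Delta\omega^2 k_{ex}}
{\dfrac{\omega_{GS}^2\omega_{ES}^2}{\omega_{eff}^2} + k_{ex}^2 -
\sin^2\theta\, p_{GS}p_{ES}\Delta\omega^2\left(1 +
\dfrac{2k_{ex}^2(p_{GS}\omega_{GS}^2 + p_{ES}\omega_{ES}^2)}
{\omega_{GS}^2\omega_{ES}^2 + \omega_{eff}^2 k_{ex}^2}\right)}$$

with $\omega_{eff}^2 = \Delta\Omega^2 + \omega_{SL}^2$,
$\omega_{GS/ES}^2 = (\Omega_{GS/ES} - \omega_{rf})^2 + \omega_{SL}^2$,
$\bar\Omega = p_{GS}\Omega_{GS} + p_{ES}\Omega_{ES}$, $\Delta\Omega =
\bar\Omega - \omega_{rf}$ and $\theta = \tan^{-1}(\omega_{SL} /
\Delta\Omega)$ (taken in $(0, \pi)$ via `atan2`, so an on-resonance
carrier gives exactly $\theta = \pi/2$). The inner fraction of the
denominator uses the effective-field magnitudes $p_{GS}\omega_{GS}^2 +
p_{ES}\omega_{ES}^2$, the grouping of the Laguerre-approximation
literature; this is the form our Bloch–McConnell oracle confirms to
sub-percent accuracy across the measurement regime. The approximation's
denominator can turn non-positive far outside its validity; that raises
an error naming the offending setting instead of clipping, so fits
cannot silently rest on nonsense values.

All model mathematics is in rad/s. File I/O and user-facing arguments
use Hz (spin-lock powers, offsets) and ppm (shifts), and every
conversion demands an explicit field declaration
(`larmor_MHz(nucleus, field_h1_MHz)`, with the ¹⁵N/¹H gyromagnetic
ratio built in) because datasets from 600 and 800 MHz spectrometers
must not be mixed implicitly.

### Numerical Bloch–McConnell oracle

`bm_evolve_r1rho()` propagates the full 6-dimensional magnetization
(x, y, z of GS and ES) under the spin-lock generator by
eigendecomposition, starting aligned along the population-averaged
effective field, and extracts the effective rate by log-linear
regression of the projection over the delay grid — the same reduction
applied to experimental decays. It is the independent numerical route
against which the closed form is tested (median deviation well under 2%
over p<sub>ES</sub> 0.5–10%, k<sub>ex</sub> 300–2000 s⁻¹, Δω 0.3–3 ppm,
spin-lock 100–500 Hz, offsets within ±3ω<sub>SL</sub>), and also the
generator of synthetic decays. GS and ES share one R1 and one R2, as in
the closed form; per-state relaxation is not modeled.

### CEST

`simulate_cest()` propagates both states' magnetization under a weak
constant B1 during the mixing time and reads out the surviving GS
z-magnetization, normalized against the same propagation with the
carrier parked at a far-off-resonance reference (−12 kHz by default), so
the baseline is exactly 1. The spin-state-selective (TROSY) character of
the experiment is deliberately not modeled at the density-matrix level:
the two detected components are modeled as sharing the plain two-site
saturation profile $P$ with component-specific transfer weights, so
their difference is a scaled saturation contrast $c\,(1 - P)$ — which is
precisely the model `fit_cest()` fits, with the exchange parameters
strictly frozen at the values from the nitrogen dispersion analysis and
only the ES position, relaxation nuisances and the contrast amplitude
free. A frozen minor population at or below 0.2% is refused as
unidentifiable. Starting values for the ES position are located from
the data by subtracting a GS-only direct-saturation shape and taking
the largest excess dip, with the sign-mirrored position as a second
start.

## Fitting strategy

Fitting is two-stage, matching experimental practice: peak-intensity
decays are first reduced to per-setting R1ρ values by mono-exponential
least squares (`fit_decay_to_r1rho()`; a variance-weighted log-linear
solve refined by Gauss–Newton, exact on clean data), with per-value
errors from 50 Monte Carlo refits of Gaussian-perturbed intensities.
The dispersion fit then minimizes error-weighted squared residuals of
the closed form over the (power, offset) grid — per residue
(`fit_r1rho_single()`) or globally with shared
(p<sub>ES</sub>, k<sub>ex</sub>) and per-probe (Δω, R1, R2)
(`fit_r1rho_global()`).

The optimizer is multistart Levenberg–Marquardt (`minpack.lm`): both
signs of Δω and a log-spaced grid of k<sub>ex</sub> starting values
guard the known ±Δω and fast/slow-exchange degeneracies. After the best
minimum is found, an all-signs-flipped refit probes the ±Δω degeneracy;
if it lands within Δχ² < 1 the result is flagged `sign_ambiguous`
(resolving the sign needs external shift prediction, out of scope
here). A no-exchange null model (weighted linear fit of
R₁cos²θ + R₂sin²θ) provides `exchange_significant`: data that do not
beat the null by the 95% χ² quantile are flagged rather than reported
as exchange. Bounds are loose physical ones: p<sub>ES</sub> ∈
(10⁻⁴, 0.5) (the ES is the minor state by convention), k<sub>ex</sub> ∈
(10, 10⁵) s⁻¹, R1 ∈ [0.1, 10] s⁻¹, R2 ∈ [1, 100] s⁻¹, Δω unbounded.

`mc_errors()` is a parametric bootstrap by default: R1ρ values are
resampled around the best-fit model curve with the measured errors and
refit from the best-fit parameters; `center = "measured"` switches to
resampling around the data. Refit failures are counted and more than
20% invalidates the estimate. All stochastic routines take explicit
seeds and restore the caller's RNG state, so results are bit-identical
under a fixed seed.

## Thermodynamics

`vant_hoff_fit()` fits $\ln(k_i(T)/T)$ against $1/T - 1/T_{hm}$ for
each direction: the slope gives ΔH‡ (× −R) and the intercept gives
ΔG‡ at the harmonic-mean temperature $T_{hm} = n / \sum_i T_i^{-1}$,
relative to the Eyring prefactor $\ln(k_B\kappa/h)$ with transmission
coefficient κ = 1. Entropies follow as TΔS‡ = ΔH‡ − ΔG‡ at $T_{hm}$ and
net GS→ES quantities as forward minus backward; both identities are
enforced to 1e-9 in tests. The fit is weighted by
$\sigma(\ln k) \approx \sigma_k / k$ when rate errors are present, and
a two-temperature series is fitted exactly but flagged (zero residual
degrees of freedom). Constants are fixed at R =
1.98720425864×10⁻³ kcal mol⁻¹ K⁻¹ and CODATA 2018 k<sub>B</sub>, h;
Celsius inputs are converted with the exact 273.15 offset; the default
single-temperature evaluation point is 283.15 K, the temperature at
which the dispersion experiments are run.

## Multi-step register-shift kinetics

The sequential mechanism — one base pair broken and re-formed per step —
is modeled as a linear chain: state free energies (GS = 0; four
intermediates; ES) and absolute transition-state energies between
neighbours. Storing barriers as absolute TS energies makes forward and
backward rates share one saddle point, so detailed balance and
Boltzmann stationarity hold by construction (verified to 1e-10/1e-8).
Rates are transition-state-theory rates $(k_BT/h)\,e^{-(TS - E_i)/RT}$.

The bundled six-state example (`six_state_chain()`) places the ES at
1.63 kcal/mol (the population free energy of the 6.2% state, treated as
a supplied constant) and the intermediates 1.27 kcal/mol above the ES —
RT·ln10 at 278.15 K, a ten-fold abundance drop that keeps them below
the dispersion detection floor. All five transition states share one
height, and the default temperature is 278.15 K, the choice under which
the ten-fold step is exact.

`apparent_two_state()` reduces the chain three ways, cross-checked
against each other:

* the **spectral** route: k<sub>ex,app</sub> is minus the slowest
  non-zero eigenvalue (computed on the detailed-balance-symmetrized
  generator for stability), with the apparent ES population taken as
  the Boltzmann mass of everything outside the GS lump — intermediates
  are assigned to the ES side, and the apparent activation energy is
  the Eyring conversion of k<sub>1,app</sub>;
* the **transition-path** route: the forward committor is solved
  exactly and `k1_tp` = flux / committor-weighted GS population. This
  is the quantity a first-passage measurement estimates; it differs
  from the eigenvalue-lump rate by O(1/spectral gap), which on the
  six-state chain is a real 10–25% — comparing a first-passage
  simulation against the bare lumped rate would conflate two different
  observables;
* the **stochastic** route: `gillespie_first_passage()` samples exact
  continuous-time Markov paths; its 1/MFPT agrees with `k1_tp` to ~1%
  at 10⁴ paths.

A spectral gap under 10× between the slowest and next mode warns that
the two-state reduction is poor. `tune_barriers()` interprets "globally
fine-tuned" minimally: one uniform additive shift on all TS energies,
bisected until the apparent ΔG‡ hits the target to 1e-4 kcal/mol (the
response is monotone and nearly 1:1). Tuned to the measured
14.74 kcal/mol, the largest individual barrier comes out at
13.97 kcal/mol and the concerted-transition sum
(`simultaneous_barrier()`, $\sum_i (TS_i - E_{i-1})$) at ~58 kcal/mol —
the same contrast, though not digit-exact, as the published
13.95/55.98 pair, whose per-step barriers are not printed; the
equal-TS-height reading is ours.

## Designing the excited state

The stem designer enumerates all combinations of the six strong pairs
(A-U, U-A, G-C, C-G, G·U, U·G) over the stem positions and applies, in
order: base-pair-triplet uniqueness — each position's (pair above,
pair, pair below) context, with cap and terminal tokens at the ends,
must be unique so imino resonances resolve in the 2D spectrum (checked
for all positions by default; a `gu_only` scope is available) — and the
ES admissibility rule: after the register shift, at most one weak pair
(G·G, U·U, G·A, A·G) and nothing outside the strong/weak sets.
`register_shift()` is deterministic and conservative: a +1 shift
re-pairs `three[i]` with `five[i+1]`, sends the bottom 5′ base to the
terminal (or bulge, in the lower-stem mode) and the top 3′ base into
the loop, growing a tetraloop into a pentaloop; interior pairs are
restored exactly by the opposite shift.

Scoring uses a pluggable energy backend. The bundled
`nn_energy_backend()` is a deliberately simple additive model —
standard Watson–Crick nearest-neighbour stack increments, approximate
wobble stacks closed under the two-strand reading symmetry, a
hairpin-loop initiation term by loop size, and a fixed 1.5 kcal/mol
penalty per weak pair which also interrupts stacking. It ranks
structures for the filter; it is not, and does not pretend to be, a
full secondary-structure energy model, and an external program's
energies can be plugged in through the same `score(pairs, loop_size)`
interface. `design_filter()` accepts a candidate when its ΔΔG (ES −
GS, including the loop-size change) is at most 3 kcal/mol — the ~0.5%
population floor at 283.15 K below which dispersion signals become
undetectable — and no scanned alternative structure undercuts the
designed ES. The alternative scan is a bounded bespoke set: register
shifts of magnitude ≤ 2 in both directions plus terminal- and
loop-closing-pair-melted variants, standing in for an external
structure-ensemble program.

## The synthetic-data generator

With no public raw dispersion data, the generators define the study
conditions: four ¹⁵N probes with downfield Δω of 1.0/1.5/2.0/2.5 ppm
(the wobble→Watson–Crick pattern), p<sub>ES</sub> = 6.2%,
k<sub>ex</sub> = 453 s⁻¹, R1 = 2 s⁻¹, R2 = 18 s⁻¹ at a 600 MHz field;
spin-lock powers {100, 150, 200, 300, 500} Hz with offsets at
{±3, ±2, ±1.5, ±1, 0}×power; eight delays over 0–70 ms; 2% Gaussian
intensity noise (multiplicative, independent across points — the 2%
default is the level at which Monte Carlo population errors land on the
0.1–0.5 point scale of reported fits). CEST truth uses two ¹H probes
(Δω +0.45 and +1.20 ppm), B1 = 15 Hz, 0.2 s mixing, the 8.5–15.5 ppm
grid in 30 Hz steps, and 0.005 additive noise on the normalized scale.
Rate series invert the van't Hoff relation exactly and add
multiplicative log-normal noise, since rates are positive and fitted in
log space.

What the generator does **not** emulate: peak overlap and assignment
errors, per-state relaxation differences, off-resonance alignment
imperfections, temperature miscalibration, or any pulse-sequence
detail. Passing recovery tests therefore demonstrates the correctness
and calibration of the analysis chain under ideal two-state physics,
not robustness to every artifact of real spectra.

### A known, quantified bias

The generator integrates the exact two-site equations; the fits use the
closed-form approximation, exactly as the experimental analysis does.
The approximation is 0.5–3% low in R1ρ where Δω approaches or exceeds
ω<sub>SL</sub> (the 100 Hz settings of the 2.5 ppm probe), and those
correlated deviations pull the recovered population down by roughly
0.2–0.3 points (6.2% → ~5.9%) and push k<sub>ex</sub> up by ~10% under
the default conditions. On self-consistent data (generated from the
closed form itself) the same pipeline is unbiased to ±0.01 points over
20 datasets. This is a property of fitting the Laguerre form to exact
exchange physics in this regime — worth remembering when reading any
dispersion study's third significant digit — and we report it rather
than hide it: the recovery experiment in `scripts/acceptance.R` prints
the measured bias and coverage as they come out.

## Numerical choices and problem sizes

Eigendecomposition is used for all matrix exponentials (6×6 exchange
generators; chain generators symmetrized by $\sqrt\pi$ similarity
before `eigen(symmetric = TRUE)`). Degenerate inputs are handled
explicitly: ΔΩ = 0 gives θ = π/2, zero mixing time gives a flat CEST
profile, flat decays give zero rate, and a single temperature is its
own harmonic mean. Ties in the design filter are broken by the
deterministic lexicographic enumeration order. The simulation sizes
used by the tests and the acceptance script — a 100-point
Laguerre-vs-BM sweep, 20 recovery datasets with 50 Monte Carlo
iterations each (the 50 matching the experimental analysis convention),
100 van't Hoff replicates, 10⁴ Gillespie paths — were chosen to hold
Monte Carlo uncertainty well below the tolerances being checked while
keeping a full run in the minutes range on one core.

## Known limitations

Two-site exchange only; no ≥3-state dispersion models. One R1/R2 pair
shared between GS and ES. The CEST model omits spin-state-selective
relaxation detail by design. The bundled energy backend's wobble stacks
are approximate, and the alternative-structure scan is bounded rather
than exhaustive — for publication-grade design decisions an external
folding program should be plugged into the backend interface. The
barrier tuner's uniform-shift reading of "globally fine-tuned" is the
minimal-parameter interpretation; per-barrier tuning is possible
through the chain constructor but not automated.
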