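---
title: "Relaxation kinetics of ligand binding: models, fitting choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxation kinetics of ligand binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxfit)
```

# The models

## Binding mechanisms and their relaxation spectra

relaxfit analyses stopped-flow fluorescence transients of ligand binding to
a trypsin-like protease under pseudo-first-order conditions — the ligand in
large excess over the enzyme, so [L] is effectively constant during the
transient. Two linear mechanisms are supported.

**Conformational selection** couples a pre-existing conformational
equilibrium E\* ⇌ E (closed/open, first-order rates k12: E\*→E and k21:
E→E\*) to binding of L by E alone (kon, koff). Linearizing the scheme gives
a 3×3 generator matrix whose two nonzero eigenvalue magnitudes are the
relaxation rates

$$2\alpha_{1,2} = k_{12}+k_{21}+k_{on}[L]+k_{off} \pm
\sqrt{(k_{on}[L]+k_{off}-k_{12}-k_{21})^2 + 4k_{21}k_{on}[L]}$$

α₁ (the + root) reflects binding and grows linearly in [L]; α₂ saturates to
k12 at high [L] and reports the conformational step. The ratio k21/k12 sets
the E\*:E partition at zero ligand.

**Lock and key** is the k12 = k21 = 0 limit: a single relaxation
α₁ = koff + kon[L].

Units are fixed package-wide: μM for concentrations (M appears only inside
ΔG), s for time, kcal/mol for energies, K for temperature; kon is therefore
μM⁻¹s⁻¹.

## Temperature dependence and thermodynamics

Each rate constant carries an Arrhenius law
k(T) = k₀ exp{−(E/R)(1/T − 1/T₀)} with T₀ = 288.15 K by default and
R = 1.9872×10⁻³ kcal/mol/K. From the fitted kon/koff laws,

- Kd = koff/kon (μM),
- ΔG = RT ln Kd with Kd expressed in M (1 M standard state — required for
  ΔG = −5.3 kcal/mol to follow from Kd = 100 μM),
- ΔH = Eon − Eoff,
- ΔS = (ΔH − ΔG)/T, reported in cal/mol/K.

ΔG = ΔH − TΔS holds to 1e−9 by construction and is asserted
property-style in the tests.

## Equilibrium assays

Chemical denaturation uses the two-state linear extrapolation method (LEM):
ΔG_fold(D) = m([GuHCl]₅₀ − D), unfolded fraction
fU = 1/(1 + exp(ΔG_fold/RT)), observed signal
(1−fU)·(folded baseline) + fU·(unfolded baseline) with linear baselines.
The source experiments only cite their fitting convention; LEM is the
standard that convention denotes, and is declared here as our concrete
choice. Cation titration uses a rectangular hyperbola
F = F₀ + ΔF_max[Na⁺]/(Kd + [Na⁺]); no Hill cooperativity is modelled, and
constant ionic strength (choline chloride replacement) is assumed.

# Numerical choices

- **Stable slow root.** The (s − d)/2 form of α₂ cancels catastrophically
  at high [L]; α₂ is computed from the exact root product
  α₁α₂ = (k12+k21)koff + k12·kon[L]. Both roots are verified against the
  eigenvalues of the generator matrix to 1e−9 relative on 1,000 random
  parameter sets.
- **Exact propagation.** Transients are propagated by the matrix
  exponential of the generator (eigendecomposition when well conditioned,
  `Matrix::expm` otherwise), projected onto per-species fluorescence
  coefficients. Default coefficients (E\* = 1.0, E = 1.0, complex = 0.7
  a.u.) mimic quenching on binding; the source data never state amplitude
  expressions, so amplitudes here are a modelling choice, configurable via
  `observable_model()`. The default initial state is the zero-ligand
  conformational equilibrium — what mixing enzyme against ligand produces.
- **Dead time as censoring.** Points earlier than the dead time (default
  1 ms) are dropped, not convolved; censoring is the conservative reading
  of a stated dead time.
- **Variable projection everywhere.** For exponential, LEM and hyperbola
  fits, the linear coefficients (baselines, amplitudes) are solved by
  linear least squares at each trial of the nonlinear parameters (rates,
  midpoint/m, Kd), which are searched on a log scale. Fits are
  deterministic given data; all stochasticity lives in the seeded
  generators.
- **Model-count selection.** The instrument software's "analysis of
  residuals" is made concrete as a nested F-test (default α = 0.01) plus
  identifiability guards: both rates positive with ratio > 1.5, finite
  standard errors, and each phase carrying > 0.5% of the signal change.
  The amplitude guard matters: on noiseless single-exponential data the
  two-exponential fit can reach machine-precision RSS with a
  zero-amplitude phantom phase. Degenerate (flat) traces fall back to one
  exponential with a warning, flagged not raised.
- **Global fit.** Unweighted RSS over all observed relaxations at once
  (no weighting scheme is stated for the source fits). Initialization is
  analytic — per-temperature linear regressions (for conformational
  selection, regressions of α₁+α₂ and α₁·α₂ on [L], with both roots of the
  resulting quadratic tried as starts) followed by Arrhenius regression —
  then Nelder–Mead and BFGS polish. Standard errors come from the
  covariance of the numeric least-squares Jacobian; published ± values are
  not reproducible without the raw data, so errors are reported but not
  acceptance-tested.
- **Mechanism discrimination.** Classified as conformational selection only
  if a majority of conditions need two exponentials *and* α₂([L]) is fit
  significantly better by a saturating curve than by a line; the
  per-temperature F-tests are pooled with Fisher's method, because a single
  six-point temperature series rarely rejects linearity alone. A
  single-row profile returns lock-and-key with a low-confidence flag.
- **Ties.** A vanishing discriminant (α₁ = α₂) is returned as equal rates
  with a degeneracy flag.

# What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure the fitters assume: the
published condition grid (ligand in the tens of μM, six temperatures
278.15–303.15 K), ~200 log-spaced points per trace over ~1 s, 1 ms dead
time, and additive homoscedastic Gaussian noise (averaged photomultiplier
traces are approximately Gaussian). Defaults are the stated world;
sample sizes were not revisited after seeing test outcomes.

It does **not** model enzyme depletion (second-order regimes), mixing
artifacts beyond the dead time, shot noise or baseline drift, photobleaching,
or induced-fit/mixed mechanisms. A green recovery test therefore establishes
that the estimators are correct and well calibrated *for data of this
structure*; it cannot establish robustness to instrument pathologies the
generator does not produce.

Generator defaults chosen once, with rationale:

- noise fraction in tests: 1–3% of the signal span as each criterion
  states, matching averaged stopped-flow practice;
- m-value 3 kcal/mol/M for synthetic denaturation curves — typical for a
  ~36 kDa globular protease; the source reports midpoints only;
- denaturant grid 0 to midpoint + 2 M (30 points), spanning both baselines;
- titration grid 0–16×Kd, spanning 0.2–3× around Kd as the fitter requires;
- conformational-selection example rates (k12 = 2, k21 = 8, kon = 1,
  koff = 5, with 8–15 kcal/mol activation energies) put the slow relaxation
  well inside a multi-second observation window.

# Known limitations

- Runtime scaling: tests and the acceptance script simulate 150-point
  traces (default 200) to stay inside CI budgets; grids are never reduced
  below the published 6×6 design.
- The published I16T ΔH/ΔS row is internally inconsistent at printed
  precision (ΔH = −17 printed vs Eon − Eoff = −20); the package reports
  what its own formulas produce and does not silently correct either
  value.
- Pseudo-first-order validity is a documented precondition, not a runtime
  check — enzyme concentration is never modelled.
- Reversibility of unfolding is assumed, not tested; three-state unfolding
  and thermal denaturation are out of scope.
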