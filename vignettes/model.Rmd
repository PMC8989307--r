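---
title: "A coupled pharmacokinetic and stem-cell lineage model of chemotherapy-induced cachexia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled pharmacokinetic and stem-cell lineage model of chemotherapy-induced cachexia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocachexia)
```

## The problem

5-fluorouracil (5-FU) chemotherapy causes skeletal-muscle wasting in mice
with a strongly nonlinear dose dependence: low daily doses track the
untreated control, intermediate doses lose some mass, and the highest
tolerated doses lose mass severely and at an accelerating rate. Two further
signatures constrain any mechanistic model: a roughly 10-day lag before
daily dosing shows an effect — with *no* matching lag in recovery once
treatment stops — and weekly oscillations of lean mass under 5-days-a-week
dosing. `chemocachexia` implements a model built around these three
signatures and the tooling to fit, probe and exploit it.

## Model structure

The pipeline has four one-way-coupled stages.

**1. Pharmacokinetics** (`pk_params()`, `simulate_pk()`). A linear
two-compartment model with first-order clearance; oral boluses are
instantaneous jumps of the plasma concentration by `1000 d / V1` µg/ml for a
dose of `d` mg/kg. Defaults (mouse 5-FU literature values):

| symbol | meaning | default | units |
|---|---|---|---|
| k10 | plasma clearance | 151.2 | /day |
| k12 | plasma→tissue transfer | 5.62 | /day |
| k21 | tissue→plasma transfer | 2.31 | /day |
| V1 | plasma distribution volume | 710 | ml/kg |
| V2 | tissue distribution volume | 100 | ml/kg |

`k10 = 151.2`/day is a ~6.6-minute plasma half-life, which makes the system
stiff on the day scale. Morphine comedication (`morphine_adjust()`) reduces
the three rates by a common 35%, leaving volumes unchanged — distribution
volumes are a property of the tissue, not of transport, and the source
observations concern clearance.

**2. Exposure averaging** (`average_exposure()`). The pharmacodynamic driver
is `y_tau(t) = (1/tau) * integral of C2 over [t - tau, t]`. Pre-treatment
history is zero (drug-naive tissue), which is what creates the observed
onset lag while leaving recovery lag-free: the window must *fill* with drug
before the effect engages, but empties passively after the last dose. `tau`
need not be an integer — the sensitivity analysis perturbs it continuously —
although the fitting grid tests integer values only.

**3. Muscle lineage** (`muscle_params()`, `simulate_host()`). Satellite
cells `S` and fibres `M` (volumes, mm³), symmetric division at rate
`nu(M) = nu0 + nu1/(1 + M/m)`, self-renewal probability
`p(M) = p0 + p1/(1 + M/m)`, fibre death `d0 M`. Defaults (CDF1 mouse growth
fit): p0 = 0.479, p1 = 0.133, nu0 = 0.087/day, nu1 = 5.591/day,
d0 = 0.05/day, m = 1000 mm³; lean mass is 0.002 g/mm³ × (S + M). The
homeostatic equilibrium is available in closed form
(`healthy_equilibrium()`): p(M*) = 1/2 gives
`M* = m (p1/(1/2 - p0) - 1) = 5333.33` mm³ and the fibre balance gives
`S* = d0 M* / nu(M*) = 274.97` mm³ — 11.22 g of lean mass at a 5.16% stem
ratio. Chemotherapy multiplies both lineage fluxes by `1 - (y_tau/Rd)^3`.
The cubic order matches the cubic spread of the dose-response data (linear
and quadratic forms cannot), and the factor is deliberately *not* clamped at
zero: exposures above the threshold `Rd` turn proliferation into loss, which
is exactly what the severe high-dose arms show. Because both equations carry
the same factor, the stem ratio S/M is only transiently disturbed, keeping
post-treatment regrowth free of the large overshoot that death-rate models
produce.

**4. Tumour** (`tumour_params()`). Exponential-linear growth
(µ0 = 0.446/day, µ1 = 116 mm³/day, sharpness η = 20, T0 = 10 mm³) with kill
proportional to the tissue concentration (κ = 0.13 ml/µg/day, chosen so that
some — not all — standard schedules push the tumour below 1 mm³). The tumour
does not feed back on the host.

### Host configurations

Young (6-week) hosts start at (S, M) = (267.5, 4732.5) mm³ — 10 g lean mass,
matching a 25 g mouse at 40% lean composition. The aging analyses in the
source literature print a slight variant (268.5, 4732.5), available as
`young_state("aging")`; the 1 mm³ discrepancy is documented, not resolved,
and the fitting variant is the default. Aged (2-year) hosts start at the
rounded equilibrium (275, 5333) mm³ with `p1` scaled to 98% of nominal
(`aged_params()`), which lowers equilibrium lean mass by 2.46% — the
"gradual ~2.5% loss" of the aged control.

## Numerical design

*Pharmacokinetics are solved exactly.* Between dosing events the linear
system is propagated by its 2×2 eigendecomposition; events are exact state
jumps. The trajectory also carries exact running integrals of C1 and C2, so
the exposure average is a cumulative-integral difference with no quadrature
error on the grid (off-grid window edges use the integral of the
piecewise-linear interpolant within one cell). A plain cumulative-trapezoid
path (`method = "trapezoid"`) exists for trajectories read back from CSV.
Mass balance — `V1 k10 ∫C1 + V1 C1 + V2 C2 = 1000 ×` total dose — holds to
machine precision and is asserted in the tests.

*The tissue stage is a forced ODE solve.* Because the pharmacokinetics are
autonomous, `y_tau` can be precomputed exactly and the distributed delay
never needs a delay solver; the muscle (and tumour) equations are integrated
with `deSolve::lsoda` (compiled right-hand sides, rtol 1e-8 / atol 1e-10 by
default) with the exposure passed as a linearly interpolated forcing on the
0.005-day output grid. Halving that grid moves day-28 lean mass by ~2e-7 g.
Muscle and tumour are integrated in *separate* solver calls: they share no
state, and a joint adaptive solve would let tumour parameters perturb the
muscle output through step-size selection — this separation is why the
lean-mass sensitivity to κ is identically zero rather than merely small.

*Fitting sweeps the threshold grid in one solve.* `fit_rd_given_tau()` is
the two-stage grid search (coarse 0.05 µg/ml over [1, 20], then 0.01 around
the coarse minimum; ties break toward smaller `Rd`; boundary minima warn).
Since all grid members share the same forcing, the SSE for the whole coarse
grid is computed by stacking independent 2-state blocks into a single banded
lsoda call — an exactness-preserving vectorization that makes the 20-seed
recovery experiment affordable. The search bounds and steps are package
choices (not from the source literature), set to bracket the reported
per-family fits (6.18 and 7.86 µg/ml) with margin and make them grid-
representable. Residuals are evaluated in grams at the observation days by
linear interpolation of the model grid. `select_global()` midpoints the two
per-family argmin windows; a half-integer midpoint is rounded toward the
daily family's argmin (arbitrary, flagged in the output).

*Sensitivities difference a jointly integrated pair.* The coefficient
`S(t) = (LM(t; (1±ε)ρ) - LM(t; ρ))/(ερ)` with ε = 1e-5 divides an
epsilon-level mass difference; integrating the nominal and perturbed blocks
as one 4-state system (shared step sequence, rtol 1e-11) makes their
truncation errors cancel in the difference. Without this, solver noise of
order 1e-8 g dominates wherever the coefficient is small. Plus- and
minus-sided differences then agree to <0.5% and match a central-difference
oracle at ε = 1e-6 to well under 1%.

## What the synthetic data emulate — and what they don't

`generate_dataset()` reproduces the *structure* of the source experiment:
one lean-mass series per dose arm (daily family 0/14/17/20/24/29/35 mg/kg;
5-on/2-off family 0/24/35/42/50/60 mg/kg), 2-day cadence, 56-day horizon
(28 treatment + 28 observation), 10 g initial lean mass. Observations are
model truth at a known (τ, R_d) plus independent Gaussian noise (default
σ = 0.2 g; the source curves are digitized means with no error model, so σ
is a free knob and the recovery experiments sweep it at 0.1 g). Identical
seeds give identical datasets and the caller's RNG state is untouched. Not
emulated: digitization artifacts, replicate variance structure (n = 5 mice
per arm; an optional per-replicate mode exists but claims no variance
model), and the mortality/dropout of the high-dose arms. Passing recovery
tests therefore shows the estimator is consistent *under the model's own
noise assumptions* — not that the model is identified by real, possibly
autocorrelated, digitized data.

## Empirical behaviour worth knowing

These are measured behaviours of the model at the default parameters, found
while building the test suite, and are asserted as such:

* The untreated young host's lean mass is not globally monotone: it
  overshoots the 11.2166 g equilibrium by ~0.7% near day 55 before settling
  (weakly oscillatory approach to equilibrium).
* The stem-ratio disruption from a 28-day schedule decays below 0.1% of the
  control about 160 days after the last dose; exposure-linked parameter
  sensitivities fall below 10% of their peaks roughly three months after
  treatment ends. Lineage-parameter (p0, p1, d0, m, ν) sensitivities persist
  indefinitely — they move the equilibrium itself.
* Sensitivity *rankings* are stated on the raw coefficient |S|: by |S| the
  lineage parameters p0, d0, p1 dominate and k21 leads the PK block; the
  relative coefficients |S̄| of the five PK parameters are mutually
  near-degenerate (~1.56 each) because each acts on lean mass only through a
  common scaling of the exposure. The plasma volume V1 cancels out of the
  tissue exposure exactly (bolus ∝ 1/V1, tissue influx ∝ V1) and has zero
  lean-mass sensitivity.
* Tumour curves for η = 20 and η = 100 agree pointwise to <2%; η = 4
  deviates by up to ~6% in a band around the exponential-to-linear
  transition and rejoins both limbs outside it.
* With the global τ = 8 window, splitting the daily dose metronomically
  (2-6 doses/day) changes the lean-mass AUC only at the 1e-4 level while
  measurably worsening tumour control — intraday structure is almost
  entirely averaged away.
* Exposure held slightly above `Rd` drives a steady muscle decline;
  exposure far above it (≥1.2 `Rd`) collapses the compartment outright, the
  regime behind the fatal high-dose arms.

## Efficacy conventions

Treatment-effect curves normalize by each trajectory's *own* day-0 value
(clinical presentation), not by the untreated control; a control-relative
diagnostic (`control_relative_reduction()`) is provided separately because
the aging analyses quote losses in that form. AUCs integrate the normalized
curves — the ratios are identical either way when initial values match — over
an explicit window, defaulting to [0, 56] days to cover both loss and
recovery; the window is a required, recorded argument so alternatives are
reproducible. Total therapeutic efficacy is higher-is-better and carries no
toxicity term, so schedules that are predicted "best" (e.g. 168 mg/kg once
weekly) may be exactly the ones toxicity would rule out; interpret alongside
the lean-mass ratio.

## Problem sizes

The test suite and experiments run at the sizes the analyses use: 56-day
horizons on a 0.005-day pharmacokinetic grid (~11,200 points), 15 candidate
windows × ~390 threshold evaluations per family fit, and a 20-replicate
recovery experiment over both schedule families at σ = 0.1 g. Longer
horizons (120-250 days) are used only where a property concerns the
post-treatment return to equilibrium.

## Known limitations

* No toxicity or mortality model: the efficacy metric will happily rank
  schedules the experimental animals did not survive.
* One-way coupling only: no cancer-induced cachexia, no host-tumour
  interaction, no immune compartment.
* Linear pharmacokinetics: no saturable clearance, oral absorption phase, or
  inter-individual variability; morphine is a permanent worst-case rate
  reduction (no acclimatization).
* Point estimates only: the grid search reports no uncertainty, matching
  the estimation procedure it reproduces.
* `p(M)` is not capped at 1; at the default parameters it never exceeds
  0.612, but exotic parameter sets violating `p0 + p1 <= 1` are rejected by
  the constructor rather than clamped.
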