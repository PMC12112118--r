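---
title: "Semiempirical hydroxyl-radical kinetics of electrochemical oxidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semiempirical hydroxyl-radical kinetics of electrochemical oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohkin)
```

## The model

Electrochemical advanced oxidation degrades dissolved organics through
hydroxyl radicals (•OH) generated at the anode. The radical is too
short-lived to measure directly, but during anodic water electrolysis it
stands in a recombination equilibrium with hydrogen peroxide
(•OH + •OH ⇌ H₂O₂), which *is* easy to measure. `ohkin` builds on that
observation in four steps.

**1. Radical dosimetry from H₂O₂.** The measured normalized H₂O₂ level is
represented as a cubic polynomial in time, `H2O2*(t) = B0 + B1 t + B2 t² +
B3 t³` (`fit_h2o2_polynomial()`), and the normalized radical level is taken
proportional to it, `OH*(t) = k · H2O2*(t)` (`oh_profile()`, `oh_star()`).
The proportionality factor `k` lumps the equilibrium constants, transport
and surface effects into a single electrode-and-current-density
characteristic; its absolute scale follows from the reference concentration,
`[•OH](t) = C0 · OH*(t)`.

**2. A lumped sequential chain.** The degradation pathway is coarse-grained
into ordered pools — parent pollutant, lumped intermediate groups, and CO₂ —
each converted to the next by a second-order reaction with •OH:

    d[parent]/dt  = −k₁ [parent][•OH]
    d[pool i]/dt  =  kᵢ₋₁ [pool i−1][•OH] − kᵢ [pool i][•OH]
    d[CO₂]/dt     =  k_last [pool last−1][•OH]

For bisphenol A the pools are BPA → P_tr (two-ring intermediates) → P_or
(one-ring intermediates) → CO₂. The chain length is arbitrary (≥ 3 pools),
so the rhodamine B system (RhB → one-ring acids → aliphatic acids → CO₂)
runs on the same engine. Backward reactions are omitted by construction:
at the current densities where the model is applicable (≳10 mA/cm²) the
electron transfer is effectively irreversible, and no reversibility hook is
provided. Adsorption and radical scavenging beyond the H₂O₂ equilibrium are
likewise outside the model: they are absorbed into the *effective* radical
level that `k` calibrates.

**3. Estimation.** Two-stage bounded nonlinear least squares mirrors how the
model is calibrated in practice: first `k` alone from the parent decay with
all step constants fixed at a literature prior of 1·10¹⁰ 1/(M·s)
(`fit_proportionality()`, optimized in log₁₀ because `k` lives around
1e-10), then the step constants jointly from all pool series with `k` fixed
(`fit_rate_constants()`). The second fit runs in a dimensionless frame —
concentrations divided by C0, time by a scaling factor (default 1·10⁻⁶ s) —
in which the constants are O(1); absolute constants come back through
`k = k*/(scaling · C0)` (`rescale_constants()`).

**4. Generalization and toxicity.** The factor `k` scales linearly with
applied current density, `k(j) = slope·j + intercept`
(`current_density_law()`, `fit_current_law()`), so one H₂O₂ experiment plus
a removal-efficiency calibration predicts the full concentration evolution
at any `j` in the supported range (`sweep_current_density()`). Mixture
toxicity is an additive toxic-unit sum over pools,
`Toxicity%(t) = 100 · Σᵢ poolᵢ*(t) · pᵢ / p_parent` with mass potency
`p = M / LC₅₀` (96-h Fathead Minnow endpoint), anchored at exactly 100% for
the untreated solution (`toxicity_profile()`).

## The exposure-transform oracle

For a fixed radical profile the chain is linear in each pool, so in the
radical *exposure* variable `u(t) = ∫ [•OH] dt` (M·s) it has an exact
closed-form solution — the classical Bateman cascade. `bateman_chain()`
implements it, including the confluent branch `uᵐ e^{−k u}` for repeated
step constants (the rhodamine chain has `k₂ = k₃` exactly), via partial
fractions with higher-order poles rather than division by rate differences;
rates are treated as repeated below a relative difference of 1e-9.
`oh_exposure()` supplies `u(t)` in closed form as the piecewise polynomial
integral. Every numerical trajectory in the test suite is checked against
`bateman_chain(u(t))`, which makes solver errors, clamping mistakes and
unit slips all visible against an independent exact reference.

## Numerical choices

* **Integrator.** Explicit Runge–Kutta 4(5) (`deSolve::ode`, method
  `"ode45"`) with `rtol = 1e-8`, `atol = 1e-10`; late-time pool values reach
  ~1e-4 in normalized units, hence the tight defaults. The mass balance
  (pools summing to 1 within 1e-6) is verified after integration, never
  imposed.
* **Clamp kinks.** The fitted polynomial may dip below zero inside its
  domain; evaluation clamps it at zero (physical non-negativity) rather than
  erroring. The integration is restarted at the polynomial's real roots so
  that no adaptive step straddles the derivative kink — without the restart
  the oracle comparison degrades from ~1e-9 to ~1e-5.
* **Domain discipline.** The polynomial is a fit, not a mechanism:
  evaluation outside `[0, t_max]` is an error, never extrapolation.
* **Conditioning.** The polynomial is fitted on time rescaled to `[0, 1]`
  and the coefficients transformed back exactly; the raw-power design at
  t ~ 1e4 s is numerically singular.
* **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`), pools
  stacked with equal weight (the data give no basis for weighting).
  Confidence intervals use the linearized covariance `s²(JᵀJ)⁻¹` with a
  Student-t quantile at `n − p` degrees of freedom — the standard choice
  when no interval method is prescribed. A parameter probed at the lower
  bound 0 is forwarded as a negligible positive rate (1e-12 dimensionless),
  the no-reaction limit.
* **Bounds.** The dimensionless constants are bounded to `[0, 10]`. A 0–1
  constraint is sometimes quoted for such normalized constants, but with
  the default scaling factor (1·10⁻⁶ s) and C0 = 1.31·10⁻⁴ M the
  calibrated first-step constant is already `k* ≈ 1.31 > 1`; the wider
  bound keeps the printed convention and the calibrated optimum
  simultaneously feasible.
* **Toxicity peak.** Discrete argmax with the earlier time winning ties —
  profiles can be flat near the maximum.

## Design choices where the design was open

* **Lumped potency.** The grouping of identified compounds into P_tr and
  P_or fixes the membership, but not how member potencies aggregate. The
  arithmetic mean is the default (a lumped pool is treated as an
  equimolar pseudo-component); `min`/`max` are available to bracket the
  optimistic and conservative readings. The toxicity anchor at t = 0 is
  exact regardless of the choice.
* **H₂O₂ normalization.** All species, H₂O₂ included, are normalized by the
  parent's initial concentration C0; any other reference would simply be
  absorbed into `k`, so the convention is the one that keeps
  `OH* = k · H2O2*` dimensionally coherent.
* **Intermediate "degradation".** Whether an intermediate has been
  "degraded" is ambiguous when it forms and decays simultaneously. Both
  readings are exposed: the net level (via the trajectory itself) and the
  formed-intermediate turnover `1 − pool(t)/cumulative inflow(t)`
  (`formed_intermediate_turnover()`). Only the turnover reading is
  consistent with >90% two-ring processing at 10 mA/cm²; at ≤5 mA/cm² the
  two readings diverge strongly, and neither is forced onto the data.
* **Cross-pollutant transfer.** Applying `k(j)` calibrated in the BPA frame
  directly to the rhodamine frame ignores the different C0 (a ~26%
  normalization mismatch in principle). The transfer scenario follows this
  usage as the method prescribes it; the predicted 3-h mineralization is
  insensitive enough for the inconsistency not to matter at the reported
  precision.

## The synthetic-data generator

`generate_measurements()` emulates the hourly sampling of a bench
degradation run: H₂O₂ from the scenario polynomial, pools from the
simulated chain, optional Gaussian noise, clipped at zero. Multiplicative
noise is the default (chromatographic/spectrophotometric errors scale with
the measured level) with σ = 0.04, matching the ~4% relative error typical
of the calibrated fits; additive noise is available for estimator-coverage
experiments. What the generator does *not* emulate: peak-area-to-
concentration conversion of GC/MS data, detection limits, irregular
sampling, and any model misspecification — the generated data follow the
lumped chain exactly. Passing recovery and coverage tests therefore
demonstrates the estimator's correctness under the model's own assumptions,
not the adequacy of the lumping for any particular real effluent.

## Problem sizes

The shipped scenarios integrate 4-pool chains over 5 h (BPA) and 3 h
(rhodamine) with output grids of 300–600 s; estimator validation uses
hourly grids (6 points × 4 pools = 24 residuals) — the replication at which
such experiments are actually run — and the coverage check uses 40 noisy
replicates. All of it runs in well under a minute on one core.

## Known limitations

Strictly sequential chains only (no branching, no radical–radical terms
beyond the folded equilibrium); nonstiff explicit integration (adequate for
the rate/exposure regimes of anodic oxidation at ≤ 25 mA/cm²); the linear
`k(j)` law is an interpolation over the calibrated 2.5–20 mA/cm² range and
degrades at low current densities where electron transfer is no longer
irreversible; LC₅₀ inputs are consumed as given (no QSAR estimation); and
the toxic-unit sum assumes additivity — no synergistic mixture effects.
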