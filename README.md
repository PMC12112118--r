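# ohkin

Semiempirical kinetics of pollutant fate during electrochemical advanced
oxidation, for environmental chemists and process engineers who need to
predict degradation outcomes — residual pollutant, intermediates,
mineralization, mixture toxicity — from simple bench measurements instead
of direct radical detection.

## The model

Hydroxyl radicals (•OH) drive anodic oxidation but are too short-lived to
measure. During water electrolysis they stand in a recombination
equilibrium with H₂O₂ (•OH + •OH ⇌ H₂O₂), so the easily measured H₂O₂
time course fixes the radical profile up to one proportionality factor:

    H2O2*(t) = B₀ + B₁t + B₂t² + B₃t³        (cubic fit to measurements)
    OH*(t)   = k · H2O2*(t),  [•OH](t) = C₀ · OH*(t)

The degradation pathway is lumped into a sequential second-order chain —
for bisphenol A: BPA → P_tr (two-ring intermediates) → P_or (one-ring
intermediates) → CO₂:

    d[BPA]/dt  = −k_S [BPA][•OH]
    d[P_tr]/dt =  k_S [BPA][•OH] − k_B [P_tr][•OH]
    d[P_or]/dt =  k_B [P_tr][•OH] − k_M [P_or][•OH]
    d[CO₂]/dt  =  k_M [P_or][•OH]

with mass conservation `BPA* + P_tr* + P_or* + CO₂* = 1`. The factor `k`
scales linearly with applied current density,
`k(j) = 6.48·10⁻¹² j + 8.55·10⁻¹²` for the calibrated electrode, which
turns one H₂O₂ experiment into predictions across operating conditions.
Mixture toxicity is an additive toxic-unit sum over pools with mass potency
`p = M/LC₅₀` (96-h Fathead Minnow), normalized to 100% for the untreated
solution.

Because the chain is linear in each pool once the radical profile is
fixed, it has an exact closed-form (Bateman) solution in the radical
exposure `u(t) = ∫[•OH]dt`; the package carries this as an independent
oracle (`bateman_chain()`) against which every numerical trajectory is
verified, including the repeated-rate (confluent) case.

## Worked example

```r
library(ohkin)

sc   <- builtin_scenario("bpa15")          # BPA, 15 mA/cm^2, calibrated constants
traj <- simulate_chain(sc$system, sc$rates, scenario_profile(sc),
                       t_grid = seq(0, 18000, by = 600))

round(100 * removal_fraction(traj, t = 18000), 1)        # 91
round(100 * mineralization_fraction(traj, 18000), 1)     # 70.8
round(traj$states[nrow(traj$states), ], 4)
#>    BPA   P_tr   P_or    CO2
#> 0.0902 0.0309 0.1712 0.7077

pot <- pool_potencies(read_tox_records(), sc$system$species)
tox <- toxicity_profile(traj, pot)
toxicity_summary(tox, traj$times)
#> $peak              104.27   (a transient rise above the initial 100%)
#> $peak_time         2400     (s; the toxicity maximum, ~40 min in)
#> $reduction_at_end  84.25    (% toxic-unit reduction after 5 h)
```

After five hours at 15 mA/cm² the model predicts 91% BPA removal and 71%
mineralization; the residual toxicity passes through a transient maximum
(the first-formed two-ring intermediates are more potent than BPA itself)
before dropping by 84% — the characteristic biphasic toxicity profile of
oxidative treatment.

Estimation runs the other way: `fit_h2o2_polynomial()` fits the H₂O₂
series, `fit_proportionality()` recovers `k` from the parent decay, and
`fit_rate_constants()` recovers the chain constants with 95% confidence
intervals and R²/RMSE/RSS per pool. `generate_measurements()` produces
synthetic measurement tables (exact or noisy, seeded) for validating that
loop end to end.

A command-line wrapper with `simulate`, `synth`, `fit-k`, `fit-rates`,
`sweep` and `toxicity` subcommands is installed at `inst/cli/ohkin`; see
`?ohkin_cli`.

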