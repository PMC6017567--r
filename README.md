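# slowbindr

Analysis of reversible and **slow-binding enzyme inhibition** from
plate-reader assays, written for the workflow used to characterize
tyrosinase inhibitors: percent-inhibition and IC50 estimation,
inhibition-mode classification with Lineweaver–Burk and Dixon diagnostics,
and progress-curve analysis of time-dependent (two-step, induced-fit)
binding. A synthetic-data generator with the same statistical structure as
the assay makes every stage testable by parameter recovery, since no raw
data are deposited for this kind of experiment.

## The models

A slow-binding inhibitor produces curved progress curves

P(t) = v_s·t + (v_i − v_s)/k_obs · (1 − exp(−k_obs·t)),

where v_i and v_s are the initial and steady-state velocities and k_obs is
the first-order approach rate. For a two-step mechanism — rapid E·I
formation with apparent constant K_i^app, then slow isomerization to E\*·I
with rates k3 (forward) and k4 (reverse) —

k_obs(I) = k4 + k3·[I]/(K_i^app + [I]),

a hyperbola whose shape separates two-step from one-step binding (where
k_obs is linear in [I]). Steady-state velocities over a substrate ×
inhibitor grid are fit globally with the competitive rate law
v = Vmax·S/(Km·(1+I/K_i)+S) and its uncompetitive / noncompetitive / mixed
alternatives, selected by AICc; the Dixon construction (1/v vs [I] lines
intersecting at −K_i) gives the field-standard K_i estimate. IC50s come
from a log-logistic fit to control-normalized percent inhibition,
100·(Δcontrol − Δinhibitor)/Δcontrol.

## Worked example

Simulate one compound — competitive, K_i = 10.3 µM, IC50 = 39.7 µM
(13.2 µM after preincubation), two-step binding with k3 = 0.0041 s⁻¹,
k4 = 0.0004 s⁻¹, K_i^app = 35.8 µM — and characterize it from the
synthetic data alone:

```r
library(slowbindr)

ts   <- two_step_params(k3 = 0.0041, k4 = 0.0004, Kiapp = 35.8)
mm   <- mm_params(Vmax = 1.5e-4, Km = 200)
mech <- mechanism_spec(mm,
                       inhibition_model("competitive", Ki = 35.8 / (1 + 375/200)),
                       two_step = ts)

curves <- simulate_progress_mechanistic(
  assay_design(inhibitor_concs = c(6.2, 12.5, 25, 50, 100),
               noise_sd = 0.01, replicates = 3, seed = 3), mech)
grid <- simulate_steady_state(
  assay_design(inhibitor_concs = c(0, 12.5, 25, 50),
               substrate_concs = 375 / c(8, 4, 2, 1),
               noise_sd = 0.02, replicates = 3, seed = 3),
  mechanism_spec(mm, inhibition_model("competitive", 10.3)))
dr <- simulate_dose_response(
  assay_design(inhibitor_concs = c(6.2, 12.5, 25, 50, 100),
               replicates = 3, seed = 3),
  dose_response_params(ic50 = 39.7))
dr_pre <- simulate_dose_response(
  assay_design(inhibitor_concs = c(6.2, 12.5, 25, 50, 100),
               replicates = 3, seed = 4),
  dose_response_params(ic50 = 13.2))

characterize_compound(progress_curves = curves, steady_state = grid,
                      dose_response = dr,
                      dose_response_preincubated = dr_pre,
                      compound_id = "cpd-2")
#> Compound cpd-2
#>   IC50 = 40.07 uM (hill 1.03)
#>   IC50 (preincubated) = 13 uM
#>   Mode: competitive (Ki = 10.3 uM global; Dixon 10 uM)
#>   Binding kinetics: two_step
#>   Two-step: k3 = 0.00552 /s, k4 = 0.000343 /s, Kiapp = 58.93 uM (Ki* = 3.447 uM)
```

Reading the report: the dose-response fits recover the generating IC50s
(40.1 vs 39.7 µM; 13.0 vs 13.2 µM — the ~3-fold potency gain on
preincubation that marks a slow binder). The velocity grid is classified
competitive with K_i essentially exact by both the global fit and the
Dixon intersections. The progress curves are called time-dependent with a
hyperbolic k_obs profile (two-step binding); the single-run k3/K_i^app
estimates scatter around their truths — the package's recovery tests
quantify that scatter over many seeds (medians within 15% at this noise
level).

## Command line

A thin wrapper over the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "slowbindr-cli.R", package = "slowbindr"))') \
  simulate --config cfg.json
# ... fit ic50 --input dose.csv --out report.json
```

CSV contracts are fixed: progress curves
`time_s, signal_au, inhibitor_um, substrate_um, replicate`; velocity grids
`substrate_um, inhibitor_um, v_au_per_s, replicate`; dose-response tables
`inhibitor_um, inhibition_pct, replicate`. Every simulated dataset gets a
JSON sidecar with its seed and generating parameters.

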