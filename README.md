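# onepointmm

Enzyme kinetic parameters from **single-time-point** measurements at
**high substrate conversion**.

Initial-rate (steady-state) conditions — converting at most 10–20% of the
substrate, or monitoring the whole progress curve — are often impractical:
discontinuous assays (HPLC, electrophoresis) make dense time courses
prohibitively slow, and substrate concentrations near the detection limit
make early readings unreliable. `onepointmm` is for enzymologists in that
situation: measure product **once** per initial substrate concentration,
even after 50–70% conversion, and still recover V and Km.

## The model

For an irreversible, uninhibited single-substrate reaction the
Henri–Michaelis–Menten equation `v = V·[S]0/(Km + [S]0)` integrates to

    t = [P]/V + (Km/V) · ln([S]0 / ([S]0 − [P]))

with the closed-form (Lambert-W) inversion
`[S](t) = Km · W((S0/Km)·exp((S0 − V·t)/Km))`. The package:

- **simulates** single-time-point sampling plans exactly (constant-time
  and constant-conversion strategies over a substrate grid);
- **quantifies the bias** of treating the chord `[P]/t` as an initial
  rate in hyperbolic / Hanes–Woolf fits (`bias_table()`): V is inflated
  mildly, Km strongly (2.2-fold at 70% conversion on the standard grid),
  and the inflation is invertible (`correct_apparent()`);
- **recovers unbiased parameters** from the same data by ordinary linear
  regression on the rearranged integrated equation
  `[P]/t = V − (Km/t)·ln([S]0/([S]0 − [P]))` (`fit_integrated()`);
- **diagnoses model violations** by comparing the two routes
  (`consistency_diagnostic()`): apparent/integrated ratios below 1 or far
  from the simulation-predicted values indicate inhibition,
  inactivation or reversibility;
- **propagates bounded experimental errors** by replicated simulation
  (`run_study()`, uniform relative or absolute error models);
- **generates synthetic chromogenic progress curves** with mixing dead
  time (`generate_fixture()`) and reduces them to single measurements
  with an exact dead-time correction (`preprocess_time_course()`).

## Worked example

Simulate a constant-time experiment (V = Km = 1, arbitrary units; shared
time chosen so the lowest of seven substrate concentrations reaches 50%
conversion), add ≤5% uniform errors, and analyse it both ways:

```r
library(onepointmm)
kp <- kinetic_parameters(V = 1, Km = 1)
d  <- simulate_design(design_spec("constant_time", target_fraction = 0.5,
                                  params = kp))
noisy <- perturb(d, error_model("relative_uniform", 0.05), seed = 42)

fit_hanes_woolf(chord_rate(noisy$measurements))
#> hanes_woolf fit (n = 7)
#>   V    = 1.122 +/- 0.035
#>   Km   = 1.508 +/- 0.093
#>   V/Km = 0.7441 +/- 0.024
fit_integrated(noisy$measurements)
#> integrated fit (n = 7)
#>   V    = 0.9762 +/- 0.031
#>   Km   = 0.9089 +/- 0.056
#>   V/Km = 1.074 +/- 0.036
```

The Hanes–Woolf fit of chord rates overestimates Km by ~50% — exactly
the inflation the noiseless bias map predicts for this plan — while the
integrated-equation fit of the *same seven numbers* lands on the true
values within noise. The comparison doubles as a model check:

```r
consistency_diagnostic(fit_hanes_woolf(chord_rate(noisy$measurements)),
                       fit_integrated(noisy$measurements), d$design)
#> Apparent/integrated consistency diagnostic
#>   V_app/V   = 1.149 (expected 1.115)
#>   Km_app/Km = 1.659 (expected 1.551)
#>   consistent with the model
```

And the apparent values alone can be corrected by inverting the bias map
for this sampling plan:

```r
correct_apparent(1.122, 1.508, d$design)
#>   V  = 1.00047 arb/arb
#>   Km = 0.966161 arb
```

A thin command-line front end over the same functions lives at
`inst/cli/onepointmm.R` (`simulate`, `biastable`, `fit`, `montecarlo`,
`correct`, `fixture`, `preprocess`).

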