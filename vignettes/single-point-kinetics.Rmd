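---
title: "Kinetic parameters from single time points at high substrate conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic parameters from single time points at high substrate conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onepointmm)
```

## The problem

Textbook determination of the Henri–Michaelis–Menten (HMM) parameters

$$v = \frac{V\,[\mathrm{S}]_0}{K_m + [\mathrm{S}]_0}$$

requires *initial* rates: product measured while only a few percent of the
substrate has been consumed, or continuous monitoring of the progress
curve. Both are impractical when the assay is discontinuous and slow
(HPLC, electrophoresis), or when the lowest usable substrate
concentration sits near the detection limit so early readings are
dominated by noise.

This package works with the opposite regime: one product reading per
initial substrate concentration, taken after a *large* fraction — up to
about 70% — of the substrate has been converted. For an irreversible,
uninhibited single-substrate reaction with stable enzyme, the progress
curve obeys the integrated rate equation

$$t = \frac{[\mathrm{P}]}{V} + \frac{K_m}{V}\,
      \ln\!\frac{[\mathrm{S}]_0}{[\mathrm{S}]_0 - [\mathrm{P}]},$$

whose closed-form inversion is the Lambert-W substrate-depletion solution

$$[\mathrm{S}](t) = K_m\, W\!\left(\frac{[\mathrm{S}]_0}{K_m}
   e^{([\mathrm{S}]_0 - V t)/K_m}\right).$$

Everything in the package rests on these two exact forms.

## What goes wrong with the chord, and by how much

With a single time point the only rate-like quantity available is the
chord $[\mathrm{P}]/t$. It underestimates the initial rate because the
reaction decelerates as substrate depletes, and it does so *more* at low
$[\mathrm{S}]_0$ (where a fixed reaction time converts a larger
fraction). Feeding chords into a hyperbolic or Hanes–Woolf fit therefore
inflates both parameters — mildly for $V$, strongly for $K_m$:

```{r bias}
bias_table(c(0.1, 0.3, 0.5, 0.7))[, c("f", "t_star", "V_app", "Km_app", "ratio")]
```

`bias_table()` simulates a *constant-time* plan: one shared reaction
time, chosen so that the lowest $[\mathrm{S}]_0$ reaches the target
conversion `f`. The alternative *constant-conversion* plan (every
concentration sampled at its own time reaching the same fraction) biases
less but is rarely practical. The bias depends on where the grid sits
relative to $K_m$: it is larger when all concentrations are below $K_m$
(`below_km_grid()`) than when all are above (`above_km_grid()`).

Because the bias map is fully determined by the sampling plan, it can be
inverted: `correct_apparent()` searches for the $(V, K_m)$ whose
noiseless simulation under the observed plan reproduces the fitted
apparent values. The surface is regenerated numerically for the actual
grid each time — a tabulated correction would be wrong on any other
grid.

## The unbiased route: regression on the integrated equation

Rearranged as

$$\frac{[\mathrm{P}]}{t} = V - \frac{K_m}{t}\,
  \ln\!\frac{[\mathrm{S}]_0}{[\mathrm{S}]_0 - [\mathrm{P}]},$$

the integrated equation is linear in
$x = t^{-1}\ln([\mathrm{S}]_0/([\mathrm{S}]_0-[\mathrm{P}]))$ with
intercept $V$ and slope $-K_m$. `fit_integrated()` runs this ordinary
regression on the very same single-time-point data and recovers the
generating parameters exactly on noiseless designs, at any conversion:

```{r integrated}
d <- simulate_design(design_spec("constant_time", target_fraction = 0.6,
                                 params = kinetic_parameters(1, 1)))
fit_integrated(d$measurements)
```

A *positive* slope cannot arise from the irreversible uninhibited model,
so it is treated as a fit failure — typically a symptom of product
inhibition or enzyme inactivation. The comparison of both routes on the
same data is itself a diagnostic: `consistency_diagnostic()` checks that
the apparent parameters exceed the integrated ones by the
simulation-predicted factors; ratios below 1, or far from expectation,
flag a model violation.

## Error propagation

Experimental uncertainty is modelled with *bounded* uniform errors —
"errors of up to m%" implies a hard bound, which excludes a Gaussian:

* `relative_uniform`: each product reading is scaled by
  $1 + U(-m, m)$, with $m$ typically 0.05 or 0.10;
* `absolute_uniform_of_lowest`: each reading receives an additive
  $U(-a, a)$ error with $a$ a fraction (typically 0.20) of the noiseless
  reading at the lowest $[\mathrm{S}]_0$ — a detection-limit model.

Errors are applied to the product readings, the quantity an assay
actually measures. Since all readings of a constant-time run share $t$,
a relative error on $[\mathrm{P}]$ and on $[\mathrm{P}]/t$ are
equivalent; for the absolute model the product reading is the natural
target. A `target = "rate"` variant perturbs true initial rates instead,
providing the control that isolates the single-point bias from the
noise itself.

`run_study()` replicates each condition (default 18 runs, the size at
which replicate sets of means stabilize to within their own standard
errors) and summarizes ranges, largest per-run standard errors and
mean ± SD (sample SD, $n-1$). The headline result survives noise: at
60% conversion with 5% errors the Hanes–Woolf means stay near the
noiseless bias (about 1.18 and 1.8 for $V$ and $K_m$) while the
integrated-equation means stay near 1.

## The synthetic progress-curve generator

`generate_fixture()` emulates a continuously monitored chromogenic
assay of the β-lactamase/nitrocefin type: defaults $V = 0.55$ µM/s
(33 µM/min), $K_m = 29$ µM, five substrate concentrations from 11 to
64 µM, 2 readings/s, additive Gaussian signal noise (SD 0.2 µM, about
2% of the lowest concentration), and a 7.5 s mixing dead time. Each
curve is followed to 99.9% conversion so that the record ends on a true
plateau — the completeness precondition of the whole analysis, and the
longest curves run several minutes at these parameters.

The dead time matters: product formed before the first reading is
invisible, so the nominal $[\mathrm{S}]_0$ overstates the substrate
remaining at the start of the record. `preprocess_time_course()` applies
the exact correction: for a complete reaction the effective
$[\mathrm{S}]_0$ is the final reading minus the first, product is
measured relative to the first reading, and the re-zeroed curve obeys
the same integrated equation with unchanged $V$ and $K_m$. One reading —
at a target conversion or a target time — is then extracted as the
single measurement. A plateau check (drift between the medians of the
final two 5% windows of the record, at most 2% of the effective
$[\mathrm{S}]_0$ by default; medians for robustness to reading noise)
rejects unfinished records.

What the generator does *not* emulate — and what passing tests therefore
do not establish for real data: enzyme inactivation, product or excess
substrate inhibition, burst/lag transients, substrate impurities, and
correlated instrument drift. On real data those appear as failed
consistency diagnostics, not as silently wrong parameters.

## Numerical choices

* The Lambert-W inversion uses the principal branch; for arguments past
  the overflow point of $e^y$ it switches to Newton iteration on
  $w + \ln w = y$. A bracketing bisection solver (`method = "bisect"`)
  is kept as an independent oracle; the two agree to $10^{-9}$ relative
  across randomized grids and the forward/inverse pair round-trips to
  the same tolerance.
* All fits are unweighted least squares in their native space — the
  simplest convention, and the one that reproduces the reference bias
  values. Standard errors for derived quantities use first-order
  (delta-method) propagation including the slope–intercept covariance.
* The hyperbolic fit is Levenberg–Marquardt, initialized from the
  Hanes–Woolf solution (fallback: $V = \max v$, $K_m =$ median
  $[\mathrm{S}]_0$), converged to ~$10^{-12}$.
* `chord_rate(round_signif = 3)` optionally rounds rates to three
  significant digits, emulating hand-computed tables; the bias-table
  reference values are reproduced to ±0.005 with this rounding.
* Measurements with $p = 0$ are dropped from the integrated regression
  with a warning (they carry no information there); the chord is 0.
* `bias_table()` at $f \to 0$ and `correct_apparent()` at vanishing
  conversion reduce to the identity, which the tests assert.
* Monte Carlo seeding: one root seed per study, sequential draws;
  perturbed product readings are clipped into $(0, [\mathrm{S}]_0)$ and
  clipping events are counted, never silent.

Problem sizes used throughout the tests and examples: 5–7 concentration
grids, 18-replicate studies, progress curves of a few hundred points —
each study completes in seconds.

## Limitations

The analysis assumes an irreversible, uninhibited, single-substrate
reaction with stable enzyme, $[\mathrm{E}]_0 \ll [\mathrm{S}]_0$, and a
reaction that reaches completion. Reversible and multi-substrate
systems, product/excess-substrate inhibition, cooperativity and
hysteresis are out of scope; the consistency diagnostic detects, but
does not model, such violations. Units are carried as labels only.
Fitting full time courses with $t$ as the independent variable is
deliberately not offered: it is highly sensitive to small errors in
$[\mathrm{S}]_0$, whereas the single-point formulation is not.
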