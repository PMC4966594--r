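---
title: "Monitoring batch glutamate fermentations with additive models and bootstrap bands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring batch glutamate fermentations with additive models and bootstrap bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The monitoring problem

Industrial glutamate fermentation is a batch process: a *Corynebacterium
glutamicum* culture is grown in a stirred fermenter for roughly 30 hours,
and the product titre is assayed offline every 2 hours from drawn samples,
while process parameters — carbon dioxide evolution rate (CER), dissolved
oxygen (DO), oxygen uptake rate (OUR), pH, stirring speed (SS) and
temperature — are logged by instruments every 6 minutes. Faults (an
agitation failure, a wrong titrant, a blocked feed) reduce yield, and the
2-hour assay cadence discovers them late. Because each run is expensive,
only a handful of normal batches are available to train any monitoring
scheme; multivariate projection methods (MPCA/MPLS) and black-box
classifiers want far more data than that.

`fermwatch` implements a small-sample alternative built from two standard
statistical tools:

1. an **additive model** (GAM) relating the offline titre to the online
   parameters, fitted on the pooled assays of a few normal batches, and
2. a **residual bootstrap** that converts the fitted model into a pointwise
   95% prediction band for titre over batch time.

During a new run, the fitted model turns every 6-minute online record into
a titre estimate. A **fault** is declared while that estimate is outside
the band; the monitor reports the start and the end of each excursion.

## The model

With `Y` the offline titre (g/L) and `X1, ..., Xp` the online parameters
sampled at the assay times, the model is

```
Y = c + s1(X1) + s2(X2) + ... + sp(Xp) + e,      e ~ N(0, sigma^2)
```

where each `sj` is a cubic regression spline (basis dimension 10, knots at
covariate quantiles, curvature penalty) and the error is homoscedastic
Gaussian. Each smooth is centred to sum to zero over the training rows, so
`c` is identifiable. Per-term smoothing parameters are chosen by
generalized cross-validation; a term's flexibility is summarized by its
effective degrees of freedom (edf), with edf = 1 the linear limit. The
ordinary linear model is the special case with every smooth forced linear
(`fit_glm()`, or `fit_gam(..., sp = rep(Inf, p))`), and the two model
classes are compared on the GCV score `N * RSS / (N - edf_total)^2` and the
adjusted R².

Backward elimination (`select_model()`) starts from all candidate
parameters and repeatedly removes the weakest term: a term that is not
significant at the 5% level (Wald-type test of its coefficient block) is
dropped outright — keeping it does not significantly improve the model —
and a nominally significant term is also dropped when its removal does not
raise the GCV score by more than a tolerance (default 5% relative), which
expresses the preference for the fewest components among models of equal
score. On fermentation data this retains fermentation time plus
oxygen-linked channels and discards pH and temperature; because the
stirring controller ties SS to oxygen demand, SS and the gas-exchange
channels are nearly interchangeable under elimination, and which of them
survives can vary with the training draw. The package's default model uses
time, DO, OUR and CER — the online channels that measure the culture
itself rather than an actuator.

Fitting is delegated to `mgcv` (cubic regression splines, `"cr"`), and the
fitted object is re-expressed in a representation this package owns: a
`"cr"` smooth is exactly the natural cubic spline through its values at the
knots, so each term is stored as (knots, values) and evaluated with
`stats::splinefun(method = "natural")`, which also extrapolates linearly
beyond the training range exactly as the basis does. This makes
`predict()` independent of the fitting backend, and makes the JSON
serialization (`gam_to_json()`) complete: a reloaded model reproduces
predictions to the last bit.

Two numerical choices matter at the training sizes this method is meant
for (4 batches × 16 assays = 64 rows):

* **GCV inflation.** Plain GCV is known to undersmooth small samples —
  with correlated covariates (OUR tracks CER closely) it happily buys
  wiggly smooths that cancel in-sample and explode out-of-sample. The
  smoothing search therefore inflates each degree of freedom by
  `gcv_gamma = 1.2` (a mild version of the usual 1.4 guard). Reported GCV
  scores are not inflated; the factor only steers the lambda search.
* **Extrapolation.** Faults push covariates far outside the training range
  (DO near zero, CER below 20 mol/m³/h). Each smooth extrapolates
  linearly with its boundary slope; this is deliberate — a saturating
  effect keeps pulling the estimate down as its covariate collapses — but
  it means the magnitude of an excursion under a fault is an extrapolation,
  not an interpolation, and is only as good as the boundary slope estimate.

## The prediction band

Write `Yhat(t)` for the fitted values and `e(t) = Y(t) - Yhat(t)` for the
residuals. For each bootstrap replicate `b = 1..B` (default `B = 1000`;
the acceptance studies in this package use `B = 200`):

1. draw errors for every training row and every band grid point with
   replacement from the residual pool;
2. form pseudo-responses `Y*(t) = Yhat(t) + e*_t` and refit the model with
   the same variables and basis, re-optimizing the smoothing parameters;
3. record the prediction errors `e'*(h) = [Yhat(h) + e*_h] - Yhat*(h)` at
   every grid point `h`.

The `100(1-alpha)%` band at grid point `h` is
`[Yhat(h) + q_{alpha/2}(h), Yhat(h) + q_{1-alpha/2}(h)]` with `q` the
per-point empirical quantiles of the `e'*(h)`; `boot_mean` records the
average refitted estimate. Replicates are seeded from deterministically
derived substreams, so a band is reproducible regardless of execution
order; failed refits are skipped, and fewer than 90% successes aborts the
construction.

The resampling pool uses the **leverage-adjusted residuals**
`e_i / sqrt(1 - h_i)`, recentred to zero mean. In-sample residuals
underestimate prediction error because the smoother has already spent its
leverage on them; resampling the raw residuals yields bands that are
systematically too narrow, and the adjustment is the standard correction in
residual-bootstrap regression.

Two details are genuinely open in this construction and are made explicit:

* **The band's covariate reference.** The error quantiles are anchored at
  a covariate trajectory. For monitoring, the package uses the
  across-training-batch mean online trajectory at each grid time
  (`reference_covariates()`), producing the familiar single band over
  batch time that all normal batches should traverse; any other reference
  (e.g. a new batch's own trajectory, the conditional-prediction reading)
  can be supplied instead, and in our simulations both give the same
  coverage within Monte-Carlo error.
* **Per-point versus pooled quantiles.** Per-grid-point quantiles are the
  default, consistent with the per-horizon error notation; `pooled = TRUE`
  pools the errors over all grid points.

The default grid is the 2-hour assay grid; `detect_faults()` interpolates
the band linearly to the 6-minute online cadence. Building the band
directly on the online grid (pass `grid_times` to `reference_covariates()`)
gives indistinguishable monitoring results in our simulations.

## Fault diagnosis

`estimate_online()` evaluates the fitted model at every online record
(clamped below at 0 g/L); `detect_faults()` flags a record as out-of-band
when the estimate is below the lower or above the upper edge, opens an
event at the first of at least `debounce` consecutive out-of-band records,
and closes it at the first of at least `debounce` consecutive in-band
records. The default `debounce = 1` flags immediately, as the bare
outside-band rule does; the acceptance studies use `debounce = 2` (12
minutes) as minimal chatter control. Events still open at stream end are
reported open-ended. Faults in parameters that are *not* model terms
remain detectable whenever they move the gas-exchange channels: the
nitrogen-substitution scenario leaves pH — not a model term and anyway held
at its setpoint by the controller — untouched, and is caught through the
depressed CER and OUR alone.

## What the synthetic generator emulates

No fermenter data are distributed with the package, so the generator
(`simulate_normal_batch()`, `inject_fault()`, `make_study_set()`) creates
batches with the statistical structure the method is designed for, at the
documented cadences (2 h offline, 6 min online, 30 h duration):

* **Gas exchange.** CER starts near 50 mol/m³/h, peaks near 170 within
  4–7 h (a gamma-shaped pulse with batch-random amplitude and timing) and
  decays to ~40, with a slow batch-random wobble; OUR tracks the same pulse
  with its own respiratory fluctuations, so the two are correlated but not
  proportional.
* **Dissolved oxygen.** DO sags from a resting level near 35% toward
  11–14% while oxygen demand peaks — the sag is synchronized with, but not
  locked to, the batch's own CER pulse — and recovers; stirring speed
  follows demand inside 400–900 rpm; pH is held at 7.1 ± 0.2 and
  temperature at 32.1 ± 0.3 °C.
* **Titre.** The truth curve is a saturating logistic time course plus
  saturating (Monod-type) contributions of DO, CER and OUR: production is
  limited by oxygen and metabolic activity when they are low and plateaus
  across the normal operating range. The batch's final titre is drawn
  bell-shaped within 75–85 g/L; the part of it not expressed through the
  gas channels enters as a whole-curve offset emerging with growth — an
  inoculum-quality effect that no online channel can explain and that the
  prediction band therefore has to cover. Offline assays add Gaussian
  noise (sd 1.5 g/L); online channels add per-channel instrument noise.

An early, simpler design made the titre a function of time alone; it is
worth recording why that fails. With a time-only truth, the pooled fit
routes all signal into the time smooth, the gas-exchange smooths shrink to
zero, and a fault that perturbs only DO/OUR/CER leaves the estimate — and
hence the monitor — blind. Genuine covariate dependence, identified by
within-batch variation (the DO sag, the CER/OUR wobbles) rather than by
between-batch level differences, is what makes the gas-exchange smooths
significant and faults visible. Conversely, strong *between-batch*
differences in covariate levels let a 4-batch fit absorb batch offsets
spuriously and shift held-out batches off the common band, so the generator
keeps batch-to-batch operating levels tight. Both halves of this tension
are properties of the method itself at n = 4 batches, not artifacts of the
generator.

The two fault scenarios are deterministic transforms of a batch; samples
outside the fault window are left bit-identical:

* `stirring_drop` — agitation collapses: in-window SS falls below 300 rpm,
  DO to a few percent of its value, CER and OUR below 20 mol/m³/h.
* `nitrogen_substitution` — NaOH replaces ammonia water: CER and OUR are
  depressed to `1 - 0.82 * severity` of their values (a nitrogen-starved
  culture's gas exchange collapses) while pH, DO, temperature and stirring
  remain in their normal bands.

In both, in-window titre increments are scaled by `1 - severity`. Because
off-window samples are untouched, the offline titre rejoins the normal
trajectory after the window — the idempotence of the transform is
prioritized over carrying the yield loss forward, which monitoring (driven
by the online channels) never sees anyway.

What passing tests on these batches do **not** show about real data:
real fermentations have autocorrelated instrument noise, drifting sensors,
phase changes and non-Gaussian assay errors, none of which are emulated;
and the generator's fault signatures are stylized step changes, whereas
real faults ramp.

## Known limitations

* **Small-sample band coverage.** With 4 training batches, the residual
  pool contains only four realizations of the batch-level offset; the
  empirical tail quantiles of such a pool cannot reliably cover a fifth,
  independent batch. In our replicated simulations the average coverage of
  the nominal 95% band on held-out batches settles near 88–90%, not 95%,
  and single unlucky batches (an extreme final titre) can fall largely
  outside the band. The leverage adjustment recovers several points of
  coverage but cannot manufacture tail information that four batches do
  not contain. Users monitoring processes with strong batch-to-batch
  variation should train on more batches or treat the band level as
  approximate.
* **Attribution under concurvity.** The online channels co-vary strongly
  with time; the split of the fitted signal among `s(T)`, `s(DO)`,
  `s(OUR)`, `s(CER)` is only as stable as the independent variation in the
  training batches, and the fault response — an extrapolation through
  those smooths — inherits that instability. In simulation the
  stirring-collapse signature (three channels moving together, far outside
  the training range) is detected with accurate start/end timing in
  roughly three quarters to nine tenths of replicates depending on the
  training draw; the subtler nitrogen signature (two channels, smaller
  excursion) in roughly half to two thirds.
* Rows are treated as independent; autocorrelated errors would call for a
  block or wild bootstrap (out of scope here).
* The band is pointwise, not simultaneous: even a perfectly calibrated
  95% band leaves ~5% of single normal points outside, which is why
  event debouncing (and not the bare pointwise rule) is advisable in
  operation.

## Problem sizes

The package's own studies — the replicated coverage measurement and the
fault injection–recovery runs in the test suite and in
`scripts/acceptance.R` — use 20 replicates of 5 batches (4 training, 1
held out), `B = 200` bootstrap refits and 95% bands. A single such
replicate takes a few seconds on one core; the full coverage study runs in
a few minutes. `B = 1000` (the construction's default) changes band
widths by well under 10% relative to `B = 200` in these conditions.

## A worked run

```{r, eval = FALSE}
library(fermwatch)

batches <- make_study_set(5, base_seed = 1)
training <- align_offline_online(batches[1:4])
fit <- fit_gam(training)   # titre ~ s(T) + s(DO) + s(OUR) + s(CER)
print(fit)

band <- build_band(fit, training, reference_covariates(batches[1:4]),
                   band_config(B = 200, seed = 42))

held_out <- batches[[5]]
report <- detect_faults(estimate_online(fit, held_out), band, debounce = 2)
cat(summarize_report(report)$text, sep = "\n")

faulty <- inject_fault(held_out, fault_spec("stirring_drop", 12.3, 18.5))
report_f <- detect_faults(estimate_online(fit, faulty), band, debounce = 2)
cat(summarize_report(report_f)$text, sep = "\n")
```
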