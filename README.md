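# fermwatch

Online fault diagnosis for batch glutamate fermentation with small sample
sets.

Batch fermentations are monitored offline (product titre assayed every 2 h)
and online (CER, DO, OUR, pH, stirring speed, temperature logged every
6 min). Faults — an agitation failure, a wrong titrant — cost yield, and
with only a handful of normal runs available there is not enough data for
the usual multivariate projection or machine-learning monitors. `fermwatch`
implements a small-sample approach: a generalized additive model (GAM) is
fitted to the pooled assays of a few normal batches,

```
Y = c + s(T) + s(DO) + s(OUR) + s(CER) + e,    e ~ N(0, sigma^2),
```

with `Y` the glutamate titre (g/L), `T` fermentation time and penalized
cubic regression splines `s(.)` whose smoothness is chosen by GCV. A
residual bootstrap (errors resampled with replacement from the
leverage-adjusted residuals, the model refitted `B` times) turns the fit
into a pointwise 95% prediction band `[Yhat + q_0.025, Yhat + q_0.975]`
over batch time. During a new run, the fitted model converts every
6-minute online record into a titre estimate; a **fault** is flagged while
the estimate is outside the band, and the monitor reports the start and
end time of every excursion.

Because no fermenter data are deposited, the package includes a
first-class synthetic batch generator that reproduces the statistical
structure of normal runs (logistic titre course with saturating
gas-exchange effects, CER pulse from ~50 to ~170 mol/m³/h, DO sag to
~10–15%, final titres 75–85 g/L) and injects two fault scenarios:
a stirring-speed collapse and a nitrogen-source substitution that leaves
pH looking normal.

## Worked example

```r
library(fermwatch)

batches  <- make_study_set(5, base_seed = 1)        # 4 training + 1 held out
training <- align_offline_online(batches[1:4])      # 64 aligned assay rows
fit      <- fit_gam(training)                       # titre ~ s(T)+s(DO)+s(OUR)+s(CER)
print(fit)
#> <ferm_gam: 4 terms, n = 64, total edf = 8.53, GCV = 6.49, adj R2 = 0.9940>
#>   s(T): edf 4.35, lambda 22.5, p 0
#>   s(DO): edf 1.19, lambda 1.86e+04, p 0.0013
#>   s(OUR): edf 1.00, lambda 9.4e+12, p 0.124
#>   s(CER): edf 1.00, lambda 1.7e+13, p 0.156

band <- build_band(fit, training, reference_covariates(batches[1:4]),
                   band_config(B = 200, seed = 42))
print(band)
#> <bootstrap_band: 16 grid points over [0, 30] h, 95% level, 200/200 replicates>

held_out <- batches[[5]]
report <- detect_faults(estimate_online(fit, held_out), band, debounce = 2,
                        batch_id = held_out$batch_id)
cat(summarize_report(report)$text, sep = "\n")
#> normal_05: no faults detected (0/301 points out of band)

faulty  <- inject_fault(held_out, fault_spec("stirring_drop", 12.3, 18.5))
report_f <- detect_faults(estimate_online(fit, faulty), band, debounce = 2,
                          batch_id = faulty$batch_id)
cat(summarize_report(report_f)$text, sep = "\n")
#> normal_05: 1 fault event(s), 63/301 points out of band
#> fault from 12.30 h to 18.60 h (duration 6.30 h), peak excursion 8.64 g/L
```

The fit explains 99.4% of titre variance on 64 rows with ~8.5 effective
degrees of freedom; the held-out normal batch stays inside the band at all
301 online records, while a stirring failure injected over 12.3–18.5 h is
flagged from 12.30 h to 18.60 h — the first sample after the window —
with a peak excursion of 8.6 g/L beyond the band edge. On the held-out
batch the model estimate tracks the measured titre with correlation 0.997
and RMSE 2.5 g/L.

Models serialize to JSON (`gam_to_json()` / `gam_from_json()`) with
bit-identical predictions on reload; bands export to CSV/JSON
(`write_band_csv()`, `band_to_json()`). A thin command-line wrapper with
`simulate`, `train` and `monitor` subcommands is installed at
`inst/cli/fermwatch.R` (exit code 2 signals detected faults).

The methods vignette
(`vignettes/fermentation-fault-monitoring.Rmd`) documents the model, the
band construction, the generator's design and the method's limitations —
in particular the small-sample coverage of the band and the attribution
instability of correlated online channels.

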