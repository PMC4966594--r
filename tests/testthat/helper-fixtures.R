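# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# A small additive-truth table and its four-term fit.
bench_table <- function() fixture("bench_table", simulate_additive_table(n = 60, seed = 42))
bench_fit <- function() fixture("bench_fit", fit_gam(bench_table()))

# One default study set (4 training + 1 held-out batch) with its aligned
# table, fit, reference trajectory and monitoring band.
study <- function() fixture("study", {
  batches <- make_study_set(5, base_seed = 1)
  tab <- align_offline_online(batches[1:4])
  fit <- fit_gam(tab)
  ref <- reference_covariates(batches[1:4])
  band <- build_band(fit, tab, ref, band_config(B = 200, seed = 501))
  list(batches = batches, tab = tab, fit = fit, ref = ref, band = band)
})

# Hand-built band with flat edges, for monitor unit tests.
flat_band <- function(lower = 10, upper = 20, times = seq(0, 30, by = 2)) {
  center <- rep((lower + upper) / 2, length(times))
  structure(list(grid_times = times, center = center,
                 lower = rep(lower, length(times)),
                 upper = rep(upper, length(times)),
                 boot_mean = center,
                 error_quantiles = data.frame(lo = lower - center,
                                              hi = upper - center),
                 alpha = 0.05, B = NA_integer_, n_success = NA_integer_),
            class = "bootstrap_band")
}

expect_all_within <- function(x, lo, hi, label = deparse(substitute(x))) {
  expect_true(all(x >= lo & x <= hi),
              label = sprintf("%s within [%g, %g] (range %g..%g)", label,
                              lo, hi, min(x), max(x)))
}
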