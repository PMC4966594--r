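test_that("empirical quantiles interpolate linearly and hit the extremes", {
  v <- c(-2, -1, 0, 1, 2)
  expect_equal(empirical_quantile(v, 0.5), 0)
  expect_equal(empirical_quantile(v, 0), -2)
  expect_equal(empirical_quantile(v, 1), 2)
  expect_equal(empirical_quantile(v, c(0.25, 0.75)), c(-1, 1))
  expect_error(empirical_quantile(numeric(0), 0.5), "empty")
  expect_error(empirical_quantile(v, 1.5), "0, 1")
})

test_that("empirical quantiles agree with the closed-form normal quantile", {
  set.seed(15)
  draws <- rnorm(10000)
  expect_equal(empirical_quantile(draws, 0.025), qnorm(0.025), tolerance = 0.05)
  expect_equal(empirical_quantile(draws, 0.975), qnorm(0.975), tolerance = 0.05)
})

test_that("band configuration is validated", {
  expect_error(band_config(B = 10), "B must be")
  expect_error(band_config(alpha = 0), "alpha")
  expect_error(band_config(alpha = 1), "alpha")
})

test_that("a perfect fit degenerates to a zero-width band", {
  tab <- data.frame(T = seq(1, 20, by = 1), DO = 30, OUR = 50, CER = 60,
                    SS = 500, pH = 7.1, Temp = 32)
  tab$glutamate <- 2 + 3 * tab$T
  fit <- suppressWarnings(fit_glm(tab, "T"))
  fit$residuals <- rep(0, fit$n) # exactly zero prediction error
  ref <- data.frame(T = c(5, 10, 15))
  expect_warning(
    band <- build_band(fit, tab, ref, band_config(B = 50, seed = 1),
                       refit = function(tb) fit),
    "zero spread")
  expect_equal(band$lower, band$center)
  expect_equal(band$upper, band$center)
})

test_that("bands are reproducible under a fixed seed", {
  fit <- bench_fit()
  tab <- bench_table()
  ref <- tab[seq(1, 60, by = 10), c("T", "DO", "OUR", "CER")]
  stub <- function(tb) fit
  b1 <- build_band(fit, tab, ref, band_config(B = 200, seed = 3), refit = stub)
  b2 <- build_band(fit, tab, ref, band_config(B = 200, seed = 3), refit = stub)
  b3 <- build_band(fit, tab, ref, band_config(B = 200, seed = 4), refit = stub)
  expect_identical(b1, b2)
  expect_false(identical(b1$lower, b3$lower))
})

test_that("with the refit stubbed out, band quantiles match the resampled residual pool", {
  # reloading from JSON drops the backend model, so the resampling pool is
  # exactly the stored raw residuals
  fit <- gam_from_json(gam_to_json(bench_fit()))
  tab <- bench_table()
  ref <- tab[c(3, 17, 29, 41, 55), c("T", "DO", "OUR", "CER")]
  stub <- function(tb) fit
  band <- build_band(fit, tab, ref, band_config(B = 4000, seed = 8),
                     refit = stub)
  # prediction errors reduce to iid draws from the residual pool, so the
  # per-point quantiles converge on the closed-form quantiles of that
  # discrete distribution: sort(pool)[ceiling(q * N)]
  pool <- sort(fit$residuals)
  n <- length(pool)
  q_lo <- pool[ceiling(0.025 * n)]
  q_hi <- pool[ceiling(0.975 * n)]
  sd_pool <- sd(pool)
  expect_lt(max(abs(band$error_quantiles$lo - q_lo)), 0.15 * sd_pool)
  expect_lt(max(abs(band$error_quantiles$hi - q_hi)), 0.15 * sd_pool)
  expect_lt(max(abs(band$boot_mean - band$center)), 1e-9)
})

test_that("band width stabilizes as the number of replicates grows", {
  fit <- gam_from_json(gam_to_json(bench_fit()))
  tab <- bench_table()
  ref <- tab[c(5, 25, 45), c("T", "DO", "OUR", "CER")]
  stub <- function(tb) fit
  w <- function(B, seed) {
    b <- build_band(fit, tab, ref, band_config(B = B, seed = seed), refit = stub)
    mean(b$upper - b$lower)
  }
  expect_lt(abs(w(2000, 21) / w(500, 22) - 1), 0.10)
})

test_that("the 80% band is nested inside the 95% band", {
  fit <- bench_fit()
  tab <- bench_table()
  ref <- tab[seq(1, 60, by = 12), c("T", "DO", "OUR", "CER")]
  stub <- function(tb) fit
  b95 <- build_band(fit, tab, ref, band_config(B = 500, alpha = 0.05, seed = 5),
                    refit = stub)
  b80 <- build_band(fit, tab, ref, band_config(B = 500, alpha = 0.20, seed = 5),
                    refit = stub)
  expect_true(all(b80$lower >= b95$lower))
  expect_true(all(b80$upper <= b95$upper))
})

test_that("band coverage of fresh draws calibrates to the nominal level", {
  # under the fitted-model assumptions the band is the pool quantile range,
  # so long-run coverage of new same-distribution deviations is 1 - alpha
  set.seed(16)
  res <- rnorm(400)
  tab <- data.frame(T = seq_len(400) / 10)
  tab$glutamate <- 10 + res
  fit <- fit_glm(tab, "T")
  ref <- data.frame(T = c(10, 20, 30))
  stub <- function(tb) fit
  for (a in c(0.05, 0.20)) {
    band <- build_band(fit, tab, ref, band_config(B = 2000, alpha = a, seed = 6),
                       refit = stub)
    new_dev <- rnorm(4000)
    centered <- band$error_quantiles
    cov <- mean(new_dev >= centered$lo[1] & new_dev <= centered$hi[1])
    expect_equal(cov, 1 - a, tolerance = 0.05)
  }
})

test_that("band coverage checks flag points outside and reject times off the grid", {
  band <- study()$band
  t <- band$grid_times
  cv <- band_covers(band, t, band$center)
  expect_true(all(cv$covered))
  expect_equal(cv$fraction, 1)
  vals <- band$center
  vals[5] <- band$upper[5] + 1
  cv2 <- band_covers(band, t, vals)
  expect_false(cv2$covered[5])
  expect_equal(sum(!cv2$covered), 1)
  expect_error(band_covers(band, max(t) + 1, 50), "outside band grid")
})

test_that("bands export to CSV and JSON and read back", {
  band <- study()$band
  path <- file.path(tempdir(), "band.csv")
  write_band_csv(band, path)
  b2 <- read_band_csv(path, alpha = band$alpha)
  expect_equal(b2$lower, band$lower, tolerance = 1e-12)
  expect_equal(b2$upper, band$upper, tolerance = 1e-12)
  expect_equal(b2$grid_times, band$grid_times)
  js <- jsonlite::fromJSON(band_to_json(band))
  expect_equal(js$center, band$center, tolerance = 1e-12)
  expect_equal(js$alpha, band$alpha)
})

test_that("too many failed refits abort the band", {
  fit <- bench_fit()
  tab <- bench_table()
  ref <- tab[1:3, c("T", "DO", "OUR", "CER")]
  k <- 0
  flaky <- function(tb) {
    k <<- k + 1
    if (k %% 2 == 0) stop("refit failed")
    fit
  }
  expect_error(build_band(fit, tab, ref, band_config(B = 50, seed = 2),
                          refit = flaky), "90%")
})
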