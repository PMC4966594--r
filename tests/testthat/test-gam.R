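test_that("spline basis penalty is symmetric and leaves straight lines unpenalized", {
  x <- sort(runif(40, 0, 10))
  bb <- suppressWarnings(build_basis(x, basis_dim = 8))
  expect_equal(dim(bb$penalty), c(8, 8))
  expect_equal(bb$penalty, t(bb$penalty))
  expect_length(bb$knots, 8)
  # coefficients of a cr smooth are its values at the knots, so a linear
  # function has coefficients a + b * knots and zero curvature penalty
  beta <- 2 + 3 * bb$knots
  expect_lt(abs(drop(t(beta) %*% bb$penalty %*% beta)), 1e-8 * sum(beta^2))
})

test_that("penalty quadratic form equals the integrated squared second derivative", {
  set.seed(31)
  x <- seq(0, 10, length.out = 50)
  bb <- build_basis(x, basis_dim = 7)
  beta <- rnorm(7)
  f <- splinefun(bb$knots, beta, method = "natural")
  grid <- seq(min(bb$knots), max(bb$knots), length.out = 4001)
  d2 <- f(grid, deriv = 2)^2
  h <- diff(grid)[1]
  # Simpson's rule; the squared second derivative is piecewise quadratic
  simpson <- h / 3 * (d2[1] + d2[4001] + 4 * sum(d2[seq(2, 4000, 2)]) +
                      2 * sum(d2[seq(3, 3999, 2)]))
  analytic <- drop(t(beta) %*% bb$penalty %*% beta)
  expect_equal(simpson, analytic, tolerance = 1e-6)
})

test_that("basis dimension is reduced with a warning when x has few distinct values", {
  expect_warning(bb <- build_basis(rep(1:5, 10), basis_dim = 10), "reduced")
  expect_length(bb$knots, 5)
})

test_that("pure-noise data yields the null-model limit", {
  # GCV occasionally spends a few edf on pure noise, so the sharp statement
  # is about typical flexibility and about explained variance staying nil
  stats <- vapply(1:5, function(s) {
    set.seed(s)
    tab <- data.frame(x = runif(200, 0, 10), glutamate = 50 + rnorm(200))
    fit <- fit_gam(tab, "x")
    c(edf = fit$terms$x$edf, r2 = adjusted_r2(fit))
  }, numeric(2))
  expect_lt(median(stats["edf", ]), 1.5)
  expect_lt(max(abs(stats["r2", ])), 0.15)
})

test_that("a single smooth recovers a known sine curve", {
  set.seed(6)
  tab <- data.frame(x = runif(200, 0, 2 * pi))
  tab$glutamate <- sin(tab$x) + rnorm(200, 0, 0.1)
  fit <- fit_gam(tab, "x")
  expect_gt(adjusted_r2(fit), 0.95)
  grid <- data.frame(x = seq(0.2, 2 * pi - 0.2, length.out = 50))
  expect_lt(max(abs(predict(fit, grid) - sin(grid$x))), 0.3)
})

test_that("the linear model recovers exact linear data", {
  tab <- data.frame(T = seq(1, 10, by = 0.5))
  tab$glutamate <- 2 + 3 * tab$T
  fit <- suppressWarnings(fit_glm(tab, "T"))
  slope <- diff(fit$terms$T$values) / diff(fit$terms$T$knots)
  expect_equal(slope, 3, tolerance = 1e-8)
  expect_equal(predict(fit, data.frame(T = 0)), 2, tolerance = 1e-8)
  expect_equal(unname(vapply(fit$terms, `[[`, numeric(1), "edf")), 1)
  expect_equal(suppressWarnings(adjusted_r2(fit)), 1, tolerance = 1e-12)
})

test_that("infinite smoothing reproduces the linear special case", {
  tab <- study()$tab
  vars <- c("T", "DO", "OUR", "CER")
  g_inf <- fit_gam(tab, vars, sp = rep(Inf, 4))
  g_lin <- fit_glm(tab, vars)
  expect_lt(max(abs(g_inf$fitted - g_lin$fitted)), 1e-6)
  grid <- tab[seq(1, 64, by = 7), ]
  expect_lt(max(abs(predict(g_inf, grid) - predict(g_lin, grid))), 1e-6)
})

test_that("predict matches the backend evaluation and the stored residuals", {
  fit <- bench_fit()
  tab <- bench_table()
  # definition of the residual
  expect_identical(tab$glutamate - predict(fit, tab), fit$residuals)
  # independent evaluation route through the fitting backend
  expect_lt(max(abs(predict(fit, tab) -
                    as.numeric(predict(fit$model, newdata = tab)))), 1e-8)
  # smooth centring: the average prediction equals the intercept
  expect_lt(abs(mean(predict(fit, tab)) - fit$intercept), 1e-8)
  expect_error(predict(fit, tab[c("T", "DO")]), "lacks model variable")
})

test_that("smooths extrapolate linearly outside the training range", {
  fit <- bench_fit()
  base <- bench_table()[1, ]
  xs <- max(bench_table()$CER) + c(10, 20, 30, 40)
  nd <- base[rep(1, 4), ]
  nd$CER <- xs
  p <- predict(fit, nd)
  expect_lt(max(abs(diff(diff(p)))), 1e-8)
})

test_that("GCV and adjusted R-squared match hand computation on a toy table", {
  tab <- data.frame(T = c(1, 2, 3, 4, 5, 6),
                    glutamate = c(2.1, 3.9, 6.2, 7.8, 10.3, 11.7))
  fit <- fit_glm(tab, "T")
  X <- cbind(1, tab$T)
  beta <- solve(t(X) %*% X, t(X) %*% tab$glutamate)
  rss <- sum((tab$glutamate - X %*% beta)^2)
  expect_equal(gcv_score(fit), 6 * rss / (6 - 2)^2, tolerance = 1e-10)
  tss <- sum((tab$glutamate - mean(tab$glutamate))^2)
  expect_equal(adjusted_r2(fit), 1 - (rss / 4) / (tss / 5), tolerance = 1e-10)
})

test_that("term significance separates signal from noise covariates", {
  fit <- bench_fit()
  p <- term_significance(fit)
  expect_named(p, c("T", "DO", "OUR", "CER"))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(p), 0.001) # all four carry strong signal here

  # a covariate equal to the response minus small noise
  set.seed(9)
  tab <- data.frame(x = runif(50, 0, 10))
  tab$glutamate <- tab$x * 3 + rnorm(50, 0, 0.2)
  expect_lt(term_significance(fit_gam(tab, "x"))[["x"]], 1e-3)
})

test_that("noise-term p-values are approximately uniform", {
  set.seed(10)
  hits <- vapply(1:500, function(i) {
    tab <- data.frame(x = runif(40, 0, 10), glutamate = rnorm(40))
    term_significance(fit_gam(tab, "x"))[["x"]] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.10)
})

test_that("a zero-variance covariate is reported with p = 1 and a warning", {
  tab <- bench_table()
  tab$Temp <- 32
  expect_warning(fit <- fit_gam(tab, c("T", "Temp")), "zero variance")
  expect_equal(term_significance(fit)[["Temp"]], 1)
  # its term contributes nothing to predictions
  expect_equal(fit$terms$Temp$values, c(0, 0))
})

test_that("exactly collinear covariates are rejected by name", {
  tab <- bench_table()
  tab$DO2 <- tab$DO
  expect_error(fit_gam(tab, c("T", "DO", "DO2")), "collinear.*DO")
  expect_error(fit_glm(tab, c("T", "DO", "DO2")), "collinear")
})

test_that("backward elimination keeps a lone informative covariate and rejects pure noise", {
  tab <- bench_table()
  kept <- select_model(tab, "T")
  expect_named(kept$terms, "T")
  set.seed(12)
  noise <- data.frame(x = runif(50, 0, 1), glutamate = rnorm(50))
  expect_error(select_model(noise, "x"), "no informative covariate")
})

test_that("backward elimination agrees with exhaustive best-subset search by GCV", {
  set.seed(13)
  n <- 60
  tab <- data.frame(T = runif(n, 0, 30), DO = runif(n, 10, 55),
                    OUR = runif(n, 40, 170), CER = runif(n, 40, 170))
  tab$glutamate <- 40 * plogis((tab$T - 12) / 4) +
    10 * sqrt(tab$CER / 40) + rnorm(n, 0, 1.5)
  cand <- c("T", "DO", "OUR", "CER")
  subsets <- unlist(lapply(1:4, function(k)
    utils::combn(cand, k, simplify = FALSE)), recursive = FALSE)
  gcvs <- vapply(subsets, function(vs) gcv_score(fit_gam(tab, vs)), numeric(1))
  best <- sort(subsets[[which.min(gcvs)]])
  sel <- select_model(tab, cand)
  expect_identical(sort(unname(names(sel$terms))), best)
  expect_identical(best, c("CER", "T"))
  log <- attr(sel, "selection_log")
  expect_s3_class(log, "data.frame")
  expect_equal(sort(log$dropped), c("DO", "OUR"))
})

test_that("fitted values are invariant to affine rescaling of a covariate", {
  tab <- study()$tab
  fit1 <- fit_gam(tab, c("T", "DO", "OUR", "CER"))
  tab2 <- tab
  tab2$DO <- 2 * tab$DO + 5
  fit2 <- fit_gam(tab2, c("T", "DO", "OUR", "CER"))
  expect_lt(max(abs(fit1$fitted - fit2$fitted)), 1e-6)
})

test_that("effective degrees of freedom are additive and bounded", {
  fit <- study()$fit
  edfs <- vapply(fit$terms, `[[`, numeric(1), "edf")
  expect_equal(fit$total_edf, 1 + sum(edfs))
  expect_true(all(edfs <= 10))
  expect_lt(abs(mean(fit$residuals)), 1e-8 * sd(fit$response))
})

test_that("smooth estimates converge to the generating functions with sample size", {
  ise <- function(n) {
    tab <- simulate_additive_table(n = n, seed = 77)
    truth <- attr(tab, "truth")
    fit <- fit_gam(tab)
    total <- 0
    for (v in c("T", "DO", "OUR", "CER")) {
      tm <- fit$terms[[v]]
      grid <- seq(quantile(tab[[v]], 0.05), quantile(tab[[v]], 0.95),
                  length.out = 100)
      fhat <- splinefun(tm$knots, tm$values, method = "natural")(grid)
      ftru <- truth[[v]](grid)
      total <- total + mean((scale(fhat, scale = FALSE) -
                             scale(ftru, scale = FALSE))^2)
    }
    total
  }
  expect_lt(ise(600), ise(60))
})

test_that("models reload from JSON with identical predictions", {
  fit <- bench_fit()
  path <- file.path(tempdir(), "model.json")
  gam_to_json(fit, path)
  fit2 <- gam_from_json(path)
  grid <- bench_table()[seq(1, 60, by = 5), ]
  expect_identical(predict(fit2, grid), predict(fit, grid))
  expect_identical(fit2$residuals, fit$residuals)
  expect_equal(fit2$gcv, fit$gcv)
  expect_equal(fit2$total_edf, fit$total_edf)
  # string input works too
  fit3 <- gam_from_json(gam_to_json(fit))
  expect_identical(predict(fit3, grid), predict(fit, grid))
})
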