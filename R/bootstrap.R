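#' Linear-interpolation empirical quantile
#'
#' Quantile of the empirical distribution of `values` with linear
#' interpolation between order statistics; `q = 0` and `q = 1` return the
#' minimum and maximum.
#'
#' @param values Non-empty numeric vector.
#' @param q Probability (or vector of probabilities) in `[0, 1]`.
#' @return Numeric quantile(s).
#' @export
empirical_quantile <- function(values, q) {
  if (!length(values)) stopf("empirical_quantile: empty input")
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1)) {
    stopf("empirical_quantile: q must lie in [0, 1]")
  }
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

#' Configuration of the bootstrap prediction band
#'
#' @param B Number of bootstrap replicates (>= 50; default 1000, the number
#'   of refitted models the band construction is designed around).
#' @param alpha Band level: a `100 * (1 - alpha)`% band (default 0.05).
#' @param seed Integer seed; each replicate uses a deterministically derived
#'   substream, so results do not depend on execution order.
#' @param grid Prediction time points in hours, or `NULL` for the offline
#'   assay grid (every 2 h over the batch duration).
#' @param pooled If `TRUE`, prediction-error quantiles are pooled over all
#'   grid points instead of computed per point (off by default; the
#'   per-point form matches the error-per-horizon construction).
#' @return An object of class `band_config`.
#' @export
band_config <- function(B = 1000, alpha = 0.05, seed = 1L, grid = NULL,
                        pooled = FALSE) {
  if (!is_count(B) || B < 50) stopf("B must be an integer >= 50")
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("alpha must lie strictly between 0 and 1")
  }
  structure(list(B = as.integer(B), alpha = alpha, seed = as.integer(seed),
                 grid = grid, pooled = isTRUE(pooled)),
            class = "band_config")
}

#' Mean online covariate trajectory across batches
#'
#' The reference (normal-operation) covariate values the band is evaluated
#' at: for each requested grid time, each online channel of each batch is
#' linearly interpolated and the values averaged across batches. `T` is the
#' grid time itself.
#'
#' @param batches List of `fermentation_batch` (typically the training
#'   batches).
#' @param grid_times Time points (h); default every 2 h up to the shortest
#'   batch.
#' @return Data.frame with columns `T`, `CER`, `DO`, `OUR`, `pH`, `SS`,
#'   `Temp`.
#' @export
reference_covariates <- function(batches, grid_times = NULL) {
  if (inherits(batches, "fermentation_batch")) batches <- list(batches)
  if (!length(batches)) stopf("no batches supplied")
  if (is.null(grid_times)) {
    horizon <- min(vapply(batches, function(b) max(b$online$time_h), numeric(1)))
    grid_times <- seq(0, horizon, by = 2)
  }
  ref <- data.frame(T = grid_times)
  for (v in ONLINE_VARS) {
    vals <- vapply(batches, function(b) {
      stats::approx(b$online$time_h, b$online[[v]], xout = grid_times,
                    rule = 2)$y
    }, numeric(length(grid_times)))
    ref[[v]] <- rowMeans(matrix(vals, nrow = length(grid_times)))
  }
  ref
}

#' Residual-bootstrap prediction band for glutamate production
#'
#' Implements the residual bootstrap around the fitted additive model: for
#' each replicate, training-row errors and grid-point errors are drawn with
#' replacement from the pooled set of fitted-model residuals; pseudo
#' responses `Y*(t) = Yhat(t) + e*_t` are refitted with the same variable
#' set and basis (smoothing parameters re-optimized), and the replicate's
#' prediction errors `e'*(h) = Y*(N+h) - Yhat*(N+h)` are recorded at every
#' grid point. The `100 * (1 - alpha)`% band at grid point `h` is
#' `[Yhat(h) + q(alpha/2), Yhat(h) + q(1 - alpha/2)]`, where `q` are
#' empirical quantiles of the replicate prediction errors, and the reported
#' bootstrap mean is the average refitted estimate.
#'
#' Resampling uses the leverage-adjusted (modified) residuals
#' `e_i / sqrt(1 - h_i)`, recentred to mean zero, rather than the raw ones:
#' in-sample residuals are deflated by the fit's leverage, and resampling
#' them unadjusted is known to give too-narrow bootstrap bands. When the fit
#' carries no hat values (e.g. a model reloaded from JSON) the raw residuals
#' are used.
#'
#' @param fit The `ferm_gam` fitted to `table`.
#' @param table The training table the fit was produced from.
#' @param reference_covariates Data.frame of model-variable values at each
#'   grid time (see [reference_covariates()]); its `T` column defines the
#'   band's time grid.
#' @param config A [band_config()].
#' @param refit Function taking a bootstrapped training table and returning
#'   a fitted object usable with `predict(obj, newdata)`; `NULL` (default)
#'   refits the model the usual way. Replicates whose refit fails are
#'   skipped; fewer than `0.9 * B` successes is an error.
#' @return An object of class `bootstrap_band`: `grid_times`, `center`,
#'   `lower`, `upper`, `boot_mean`, `error_quantiles` (per-point data.frame
#'   `lo`, `hi`), `alpha`, `B`, `n_success`.
#' @export
build_band <- function(fit, table, reference_covariates,
                       config = band_config(), refit = NULL) {
  stopifnot(inherits(fit, "ferm_gam"), inherits(config, "band_config"))
  missing_v <- setdiff(fit$variables, names(reference_covariates))
  if (length(missing_v)) {
    stopf("reference covariates lack model variable(s): %s",
          paste(missing_v, collapse = ", "))
  }
  ref <- reference_covariates
  grid_times <- ref$T
  n <- fit$n
  res <- fit$residuals
  hat <- if (inherits(fit$model, "gam")) {
    fit$model$hat
  } else if (inherits(fit$model, "lm")) {
    stats::hatvalues(fit$model)
  } else {
    NULL
  }
  if (!is.null(hat) && length(hat) == n && all(is.finite(hat)) &&
      all(hat < 1)) {
    res <- res / sqrt(1 - hat)
    res <- res - mean(res)
  }
  center <- predict(fit, ref)
  H <- length(grid_times)

  if (stats::sd(res) == 0) {
    warnf("residuals have zero spread: band degenerates to width 0")
  }
  if (is.null(refit)) {
    refit <- default_refit(fit)
  }

  err <- matrix(NA_real_, nrow = config$B, ncol = H)
  pred <- matrix(NA_real_, nrow = config$B, ncol = H)
  ok <- logical(config$B)
  for (b in seq_len(config$B)) {
    draw <- with_seed(derive_seed(config$seed, b), {
      list(eps_t = sample(res, n, replace = TRUE),
           eps_h = sample(res, H, replace = TRUE))
    })
    boot_table <- table
    boot_table$glutamate <- fit$fitted + draw$eps_t
    y_star_grid <- center + draw$eps_h
    fit_star <- tryCatch(refit(boot_table), error = function(e) NULL)
    if (is.null(fit_star)) next
    p_star <- tryCatch(as.numeric(stats::predict(fit_star, newdata = ref)),
                       error = function(e) NULL)
    if (is.null(p_star) || length(p_star) != H || anyNA(p_star)) next
    pred[b, ] <- p_star
    err[b, ] <- y_star_grid - p_star
    ok[b] <- TRUE
  }
  n_success <- sum(ok)
  if (n_success < 0.9 * config$B) {
    stopf("only %d of %d bootstrap refits succeeded (< 90%%)",
          n_success, config$B)
  }
  err <- err[ok, , drop = FALSE]
  pred <- pred[ok, , drop = FALSE]

  if (config$pooled) {
    qs <- empirical_quantile(as.numeric(err),
                             c(config$alpha / 2, 1 - config$alpha / 2))
    lo <- rep(qs[1], H)
    hi <- rep(qs[2], H)
  } else {
    lo <- apply(err, 2, empirical_quantile, q = config$alpha / 2)
    hi <- apply(err, 2, empirical_quantile, q = 1 - config$alpha / 2)
  }

  structure(list(grid_times = grid_times, center = center,
                 lower = center + lo, upper = center + hi,
                 boot_mean = colMeans(pred),
                 error_quantiles = data.frame(lo = lo, hi = hi),
                 alpha = config$alpha, B = config$B, n_success = n_success,
                 reference = ref),
            class = "bootstrap_band")
}

# Default bootstrap refit: same model class, same formula (variable set and
# basis), smoothing parameters re-optimized on the bootstrapped responses.
default_refit <- function(fit) {
  if (!is.null(fit$model) && inherits(fit$model, "gam")) {
    form <- stats::formula(fit$model)
    function(tb) mgcv::gam(form, data = tb, method = "GCV.Cp",
                           gamma = fit$gcv_gamma %||% 1.2)
  } else if (!is.null(fit$model) && inherits(fit$model, "lm")) {
    form <- stats::formula(fit$model)
    function(tb) stats::lm(form, data = tb)
  } else {
    function(tb) fit_gam(tb, fit$variables, basis_dim = fit$basis_dim)
  }
}

#' @export
print.bootstrap_band <- function(x, ...) {
  cat(sprintf("<bootstrap_band: %d grid points over [%g, %g] h, %g%% level, %d/%d replicates>\n",
              length(x$grid_times), min(x$grid_times), max(x$grid_times),
              100 * (1 - x$alpha), x$n_success, x$B))
  invisible(x)
}

# Linear interpolation of the band edges/center at arbitrary times inside
# the grid range.
interpolate_band <- function(band, times) {
  rng <- range(band$grid_times)
  if (any(times < rng[1] - 1e-9) || any(times > rng[2] + 1e-9)) {
    stopf("time(s) outside band grid range [%g, %g] h", rng[1], rng[2])
  }
  list(lower = stats::approx(band$grid_times, band$lower, xout = times,
                             rule = 2)$y,
       center = stats::approx(band$grid_times, band$center, xout = times,
                              rule = 2)$y,
       upper = stats::approx(band$grid_times, band$upper, xout = times,
                             rule = 2)$y)
}

#' Does the band cover the given values?
#'
#' @param band A `bootstrap_band`.
#' @param times Time points (h) inside the band grid range; the band is
#'   linearly interpolated between grid points.
#' @param values Values to check (g/L), same length as `times`.
#' @return List with `covered` (logical per point) and `fraction`.
#' @export
band_covers <- function(band, times, values) {
  stopifnot(inherits(band, "bootstrap_band"), length(times) == length(values))
  edges <- interpolate_band(band, times)
  covered <- values >= edges$lower - 1e-9 & values <= edges$upper + 1e-9
  list(covered = covered, fraction = mean(covered))
}

#' Export a band as CSV
#'
#' Columns `time_h`, `lower`, `center`, `boot_mean`, `upper`, full precision.
#'
#' @param band A `bootstrap_band`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_band_csv <- function(band, path) {
  d <- data.frame(time_h = band$grid_times, lower = band$lower,
                  center = band$center, boot_mean = band$boot_mean,
                  upper = band$upper)
  d[] <- lapply(d, function(col) format(col, digits = 17, trim = TRUE,
                                        scientific = FALSE))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a band written by [write_band_csv()]
#'
#' @param path CSV file.
#' @param alpha Band level recorded on the object (the CSV itself does not
#'   carry it).
#' @return A `bootstrap_band` (without replicate-level details).
#' @export
read_band_csv <- function(path, alpha = 0.05) {
  d <- utils::read.csv(path)
  need <- c("time_h", "lower", "center", "boot_mean", "upper")
  missing_c <- setdiff(need, names(d))
  if (length(missing_c)) {
    stopf("band file lacks column(s): %s", paste(missing_c, collapse = ", "))
  }
  structure(list(grid_times = d$time_h, center = d$center, lower = d$lower,
                 upper = d$upper, boot_mean = d$boot_mean,
                 error_quantiles = data.frame(lo = d$lower - d$center,
                                              hi = d$upper - d$center),
                 alpha = alpha, B = NA_integer_, n_success = NA_integer_),
            class = "bootstrap_band")
}

#' Export a band as JSON
#'
#' @param band A `bootstrap_band`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
band_to_json <- function(band, path = NULL) {
  payload <- band[c("grid_times", "center", "lower", "upper", "boot_mean",
                    "alpha", "B", "n_success")]
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17))
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
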