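#' Cubic regression-spline basis and curvature penalty
#'
#' Builds the basis used by the additive model for one covariate: a cubic
#' regression spline with knots at quantiles of the observed values, together
#' with the curvature penalty matrix whose quadratic form in the basis
#' coefficients equals the integrated squared second derivative of the
#' spline. The penalty is symmetric positive semidefinite and its null space
#' contains constants and linear trends, so a straight line is unpenalized.
#'
#' @param x Numeric covariate values (at least `basis_dim` distinct values,
#'   otherwise the dimension is reduced with a warning).
#' @param basis_dim Number of basis functions (= number of knots).
#' @return List with `X` (design matrix, one row per value of `x`), `penalty`
#'   (`basis_dim` x `basis_dim` curvature matrix) and `knots`.
#' @export
build_basis <- function(x, basis_dim = 10) {
  if (!is.numeric(x) || !length(x)) stopf("x must be a non-empty numeric vector")
  n_distinct <- length(unique(x))
  k <- basis_dim
  if (n_distinct < k) {
    k <- max(3L, n_distinct)
    warnf("only %d distinct values: basis_dim reduced from %d to %d",
          n_distinct, basis_dim, k)
  }
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k),
                        data = data.frame(x = x),
                        absorb.cons = FALSE, scale.penalty = FALSE)[[1]]
  list(X = sm$X, penalty = sm$S[[1]], knots = sm$xp)
}

# Partition requested variables by how they can enter the model.
partition_variables <- function(table, variables, basis_dim) {
  info <- lapply(variables, function(v) {
    ux <- unique(table[[v]])
    if (length(ux) == 1L) {
      list(var = v, type = "degenerate", k = 0L)
    } else if (length(ux) < 4L) {
      list(var = v, type = "linear", k = 1L)
    } else {
      k <- min(basis_dim, length(ux))
      if (k < basis_dim) {
        warnf("variable '%s': only %d distinct values, basis_dim reduced to %d",
              v, length(ux), k)
      }
      list(var = v, type = "smooth", k = as.integer(k))
    }
  })
  names(info) <- variables
  info
}

check_collinear <- function(table, variables) {
  num_vars <- variables[vapply(variables, function(v)
    stats::sd(table[[v]]) > 0, TRUE)]
  if (length(num_vars) < 2) return(invisible())
  cm <- stats::cor(table[num_vars])
  bad <- which(abs(cm) > 1 - 1e-12 & upper.tri(cm), arr.ind = TRUE)
  if (nrow(bad)) {
    pairs <- apply(bad, 1, function(ij)
      paste(num_vars[ij[1]], num_vars[ij[2]], sep = " ~ "))
    stopf("singular design: collinear variables (%s)", paste(pairs, collapse = "; "))
  }
  invisible()
}

# Extract the package's additive-model container from a fitted mgcv::gam or
# stats::lm. Every smooth term is recorded as the natural cubic spline
# through its values at the knots; linear terms as a 2-knot spline (i.e. a
# straight line), so a single evaluation rule serves both model classes.
as_ferm_gam <- function(model, table, variables, info, basis_dim, pvals) {
  n <- nrow(table)
  term_mat <- stats::predict(model, newdata = table, type = "terms")
  fitted_model <- as.numeric(stats::predict(model, newdata = table))
  active <- names(info)[vapply(info, function(i) i$type != "degenerate", TRUE)]
  intercept <- mean(fitted_model - rowSums(term_mat))

  smooth_edf <- NULL
  smooth_sp <- NULL
  if (inherits(model, "gam")) {
    smooth_edf <- vapply(model$smooth, function(s)
      sum(model$edf[s$first.para:s$last.para]), numeric(1))
    names(smooth_edf) <- vapply(model$smooth, function(s) s$term, character(1))
    # when smoothing parameters are fixed by the caller, mgcv reports them in
    # full.sp rather than sp
    smooth_sp <- if (length(model$sp)) model$sp else model$full.sp
    if (length(smooth_sp) != length(smooth_edf)) {
      smooth_sp <- rep(NA_real_, length(smooth_edf))
    }
    names(smooth_sp) <- names(smooth_edf)
  }

  terms <- lapply(variables, function(v) {
    inf <- info[[v]]
    if (inf$type == "degenerate") {
      return(list(variable = v, knots = table[[v]][1] + c(0, 1),
                  values = c(0, 0), edf = 1, lambda = Inf,
                  p_value = pvals[[v]]))
    }
    if (inf$type == "smooth") {
      sm <- model$smooth[[which(vapply(model$smooth, function(s)
        s$term == v, TRUE))]]
      knots <- as.numeric(sm$xp)
      col <- paste0("s(", v, ")")
    } else {
      knots <- range(table[[v]])
      col <- v
    }
    nd <- table[rep(1L, length(knots)), active, drop = FALSE]
    nd[[v]] <- knots
    values <- as.numeric(stats::predict(model, newdata = nd,
                                        type = "terms")[, col])
    edf <- if (inf$type == "smooth") unname(smooth_edf[v]) else 1
    lambda <- if (inf$type == "smooth") unname(smooth_sp[v]) else Inf
    list(variable = v, knots = knots, values = values, edf = edf,
         lambda = lambda, p_value = pvals[[v]])
  })
  names(terms) <- variables

  fit <- structure(list(intercept = intercept, terms = terms,
                        variables = variables, basis_dim = basis_dim,
                        n = n, response = table$glutamate),
                   class = "ferm_gam")
  fit$fitted <- predict(fit, table)
  fit$residuals <- table$glutamate - fit$fitted
  fit$total_edf <- 1 + sum(vapply(terms, `[[`, numeric(1), "edf"))
  rss <- sum(fit$residuals^2)
  fit$sigma2 <- rss / (n - fit$total_edf)
  fit$gcv <- n * rss / (n - fit$total_edf)^2
  tss <- sum((table$glutamate - mean(table$glutamate))^2)
  fit$adj_r2 <- 1 - (rss / (n - fit$total_edf)) / (tss / (n - 1))
  fit$model <- model
  fit
}

#' Fit the additive fermentation model
#'
#' Penalized least-squares fit of
#' `glutamate = c + s(X1) + s(X2) + ... + e` with cubic regression-spline
#' smooths (knots at covariate quantiles), per-term smoothing parameters
#' chosen to minimize the GCV score, and sum-to-zero centring of each smooth
#' so the intercept is identifiable. Errors are Gaussian with constant
#' variance.
#'
#' @param table Training table from [align_offline_online()] (or any
#'   data.frame with a `glutamate` column and the model covariates).
#' @param variables Covariate names to include as smooth terms.
#' @param basis_dim Basis dimension per smooth (default 10).
#' @param sp Optional vector of fixed smoothing parameters, one per variable
#'   (in `variables` order). `Inf` forces a term to its linear limit;
#'   `NULL` (default) selects all by GCV.
#' @param gcv_gamma Inflation factor on each model degree of freedom in the
#'   GCV criterion used for smoothing selection. Plain GCV (`gcv_gamma = 1`)
#'   is known to undersmooth at training sizes of a few dozen rows,
#'   especially with correlated covariates such as OUR and CER; the default
#'   1.2 is a mild version of the standard guard against that. Reported GCV
#'   scores and edf are unaffected by the inflation, which only steers the
#'   lambda search.
#' @return An object of class `ferm_gam`: intercept, per-term spline
#'   representation (knots, values, edf, lambda, p-value), residuals, fitted
#'   values, `sigma2`, `gcv`, `adj_r2` and `total_edf`.
#' @export
fit_gam <- function(table, variables = c("T", "DO", "OUR", "CER"),
                    basis_dim = 10, sp = NULL, gcv_gamma = 1.2) {
  missing_v <- setdiff(c(variables, "glutamate"), names(table))
  if (length(missing_v)) {
    stopf("table lacks column(s): %s", paste(missing_v, collapse = ", "))
  }
  if (!length(variables)) stopf("at least one variable is required")
  if (nrow(table) < length(variables) + 2) {
    stopf("need at least %d rows to fit %d terms", length(variables) + 2,
          length(variables))
  }
  check_collinear(table, variables)
  info <- partition_variables(table, variables, basis_dim)
  types <- vapply(info, `[[`, character(1), "type")
  if (all(types == "degenerate")) stopf("all covariates are constant")

  rhs <- vapply(variables[types != "degenerate"], function(v) {
    if (info[[v]]$type == "smooth") {
      sprintf("s(%s, bs = 'cr', k = %d)", v, info[[v]]$k)
    } else {
      v
    }
  }, character(1))
  form <- stats::as.formula(paste("glutamate ~", paste(rhs, collapse = " + ")))

  sp_use <- NULL
  if (!is.null(sp)) {
    if (length(sp) != length(variables)) {
      stopf("sp must have one entry per variable")
    }
    names(sp) <- variables
    sp_use <- sp[variables[types == "smooth"]]
    sp_use[!is.finite(sp_use)] <- 1e12 # effectively linear
  }
  g <- mgcv::gam(form, data = table, method = "GCV.Cp", sp = sp_use,
                 gamma = gcv_gamma)

  smry <- summary(g)
  pvals <- as.list(rep(1, length(variables)))
  names(pvals) <- variables
  for (v in variables) {
    if (types[[v]] == "smooth") {
      pvals[[v]] <- unname(smry$s.table[paste0("s(", v, ")"), "p-value"])
    } else if (types[[v]] == "linear") {
      pvals[[v]] <- unname(smry$p.table[v, "Pr(>|t|)"])
    } else {
      warnf("variable '%s' has zero variance; p-value reported as 1", v)
    }
  }
  fit <- as_ferm_gam(g, table, variables, info, basis_dim, pvals)
  fit$gcv_gamma <- gcv_gamma
  fit
}

#' Fit the linear special case
#'
#' Ordinary least squares on the raw covariates: the additive model with
#' every smooth forced to one effective degree of freedom. Returned in the
#' same container as [fit_gam()], with each term's edf equal to 1, so the
#' two model classes can be compared by GCV score and adjusted R-squared.
#'
#' @inheritParams fit_gam
#' @return A `ferm_gam` with all-linear terms.
#' @export
fit_glm <- function(table, variables = c("T", "DO", "OUR", "CER")) {
  missing_v <- setdiff(c(variables, "glutamate"), names(table))
  if (length(missing_v)) {
    stopf("table lacks column(s): %s", paste(missing_v, collapse = ", "))
  }
  if (nrow(table) < length(variables) + 2) {
    stopf("need at least %d rows to fit %d terms", length(variables) + 2,
          length(variables))
  }
  check_collinear(table, variables)
  info <- partition_variables(table, variables, basis_dim = 2)
  types <- vapply(info, `[[`, character(1), "type")
  for (v in variables) {
    if (types[[v]] != "degenerate") info[[v]]$type <- "linear"
  }
  active <- variables[types != "degenerate"]
  if (!length(active)) stopf("all covariates are constant")
  form <- stats::as.formula(paste("glutamate ~", paste(active, collapse = " + ")))
  l <- stats::lm(form, data = table)
  if (anyNA(stats::coef(l))) {
    bad <- names(stats::coef(l))[is.na(stats::coef(l))]
    stopf("singular design: collinear variables (%s)", paste(bad, collapse = ", "))
  }
  smry <- summary(l)
  pvals <- as.list(rep(1, length(variables)))
  names(pvals) <- variables
  for (v in active) pvals[[v]] <- unname(smry$coefficients[v, "Pr(>|t|)"])
  for (v in variables[types == "degenerate"]) {
    warnf("variable '%s' has zero variance; p-value reported as 1", v)
  }
  as_ferm_gam(l, table, variables, info, basis_dim = 2, pvals)
}

#' Predict glutamate production from a fitted additive model
#'
#' Evaluates `c + sum_j s_j(x_j)`: each smooth is the natural cubic spline
#' through its stored knot values, extended linearly outside the training
#' range, so prediction is well defined (if extrapolated) for covariate
#' values beyond those seen in training. Deterministic.
#'
#' @param object A `ferm_gam`.
#' @param newdata Data.frame containing every model variable.
#' @param ... Unused.
#' @return Numeric vector of estimated glutamate production, g/L.
#' @export
predict.ferm_gam <- function(object, newdata, ...) {
  missing_v <- setdiff(object$variables, names(newdata))
  if (length(missing_v)) {
    stopf("newdata lacks model variable(s): %s", paste(missing_v, collapse = ", "))
  }
  est <- rep(object$intercept, nrow(newdata))
  for (tm in object$terms) {
    f <- stats::splinefun(tm$knots, tm$values, method = "natural")
    est <- est + f(newdata[[tm$variable]])
  }
  est
}

#' @export
print.ferm_gam <- function(x, ...) {
  cat(sprintf("<ferm_gam: %d terms, n = %d, total edf = %.2f, GCV = %.3g, adj R2 = %.4f>\n",
              length(x$terms), x$n, x$total_edf, x$gcv, x$adj_r2))
  for (tm in x$terms) {
    cat(sprintf("  s(%s): edf %.2f, lambda %.3g, p %.3g\n",
                tm$variable, tm$edf, tm$lambda, tm$p_value))
  }
  invisible(x)
}

#' Generalized cross-validation score of a fit
#'
#' `GCV = N * RSS / (N - total_edf)^2`, the score minimized during smoothing
#' selection and used to compare candidate models.
#'
#' @param fit A `ferm_gam`.
#' @return The GCV score (single number, > 0 unless residuals are all zero).
#' @export
gcv_score <- function(fit) {
  stopifnot(inherits(fit, "ferm_gam"))
  if (fit$total_edf >= fit$n) {
    stopf("model is over-saturated: total edf (%.2f) >= N (%d)",
          fit$total_edf, fit$n)
  }
  fit$n * sum(fit$residuals^2) / (fit$n - fit$total_edf)^2
}

#' Adjusted R-squared of a fit
#'
#' `1 - (RSS / (N - total_edf)) / (TSS / (N - 1))`.
#'
#' @param fit A `ferm_gam`.
#' @return Adjusted R-squared (<= 1).
#' @export
adjusted_r2 <- function(fit) {
  stopifnot(inherits(fit, "ferm_gam"))
  if (fit$total_edf >= fit$n) {
    stopf("model is over-saturated: total edf (%.2f) >= N (%d)",
          fit$total_edf, fit$n)
  }
  rss <- sum(fit$residuals^2)
  tss <- sum((fit$response - mean(fit$response))^2)
  1 - (rss / (fit$n - fit$total_edf)) / (tss / (fit$n - 1))
}

#' Per-term significance of the smooth terms
#'
#' Wald-type test of each term's coefficient block against zero on its
#' effective degrees of freedom (for linear terms, the usual t-test).
#'
#' @param fit A `ferm_gam`.
#' @return Named numeric vector of p-values in `[0, 1]`.
#' @export
term_significance <- function(fit) {
  stopifnot(inherits(fit, "ferm_gam"))
  p <- vapply(fit$terms, `[[`, numeric(1), "p_value")
  names(p) <- vapply(fit$terms, `[[`, character(1), "variable")
  pmin(pmax(p, 0), 1)
}

#' Backward model selection over candidate covariates
#'
#' Starts from the full additive model and repeatedly removes the least
#' useful term: at each step the candidate terms are examined in order of
#' decreasing p-value, and a term is dropped if it is not significant at
#' `alpha` (the model is not significantly improved by keeping it), or if
#' its removal does not increase the GCV score by more than `gcv_tol`
#' (relative) - the latter implements the preference for the model with the
#' fewest components among those with lowest GCV and highest adjusted
#' R-squared. Selection stops when no removal is acceptable.
#'
#' @param table Training table.
#' @param candidate_variables Character vector of candidate covariates.
#' @param alpha Significance level for terms (default 0.05).
#' @param gcv_tol Maximal tolerated relative GCV increase when dropping a
#'   term (default 0.05; a spuriously flexible noise term can raise GCV
#'   slightly on removal, so the guard is only against material increases).
#' @param basis_dim Basis dimension per smooth.
#' @return The reduced `ferm_gam`; the dropped-term history is attached as
#'   attribute `"selection_log"` (a data.frame).
#' @export
select_model <- function(table, candidate_variables, alpha = 0.05,
                         gcv_tol = 0.05, basis_dim = 10) {
  if (!length(candidate_variables)) stopf("at least one candidate is required")
  current <- candidate_variables
  fit <- fit_gam(table, current, basis_dim = basis_dim)
  log <- data.frame(step = integer(), dropped = character(),
                    p_value = numeric(), gcv_before = numeric(),
                    gcv_after = numeric())
  step <- 0L
  repeat {
    if (length(current) == 1L) {
      if (term_significance(fit)[[1]] > alpha) {
        stopf("no informative covariate: last term '%s' is not significant (p = %.3g)",
              current, term_significance(fit)[[1]])
      }
      break
    }
    p <- term_significance(fit)
    dropped <- FALSE
    for (v in names(sort(p, decreasing = TRUE))) {
      reduced <- setdiff(current, v)
      fit2 <- fit_gam(table, reduced, basis_dim = basis_dim)
      if (p[[v]] > alpha ||
          gcv_score(fit2) <= gcv_score(fit) * (1 + gcv_tol)) {
        step <- step + 1L
        log <- rbind(log, data.frame(step = step, dropped = v,
                                     p_value = p[[v]],
                                     gcv_before = gcv_score(fit),
                                     gcv_after = gcv_score(fit2)))
        current <- reduced
        fit <- fit2
        dropped <- TRUE
        break
      }
      if (p[[v]] <= alpha) break # significant and GCV-supported: keep the rest
    }
    if (!dropped) break
  }
  attr(fit, "selection_log") <- log
  fit
}

#' Residual diagnostics for a fitted model
#'
#' Computes the ingredients of the standard diagnostic panel: normal Q-Q
#' pairs of the residuals, residual histogram counts, (fitted, residual)
#' pairs, (measured, estimated) pairs, and the Pearson correlation and RMSE
#' between measured and estimated production. With `newdata` (e.g. the
#' held-out test batch rows) the measured/estimated comparison is evaluated
#' there instead of on the training rows.
#'
#' @param fit A `ferm_gam`.
#' @param newdata Optional table with `glutamate` and the model covariates.
#' @return List with `qq` (data.frame `theoretical`, `sample`), `histogram`
#'   (`breaks`, `counts`), `fitted_residual`, `measured_estimated`,
#'   `correlation` and `rmse`.
#' @export
residual_diagnostics <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "ferm_gam"))
  if (is.null(newdata)) {
    measured <- fit$response
    estimated <- fit$fitted
  } else {
    measured <- newdata$glutamate
    estimated <- predict(fit, newdata)
  }
  res <- measured - estimated
  n <- length(res)
  h <- graphics::hist(fit$residuals, plot = FALSE)
  list(qq = data.frame(theoretical = stats::qnorm(stats::ppoints(fit$n)),
                       sample = sort(fit$residuals)),
       histogram = list(breaks = h$breaks, counts = h$counts),
       fitted_residual = data.frame(fitted = fit$fitted,
                                    residual = fit$residuals),
       measured_estimated = data.frame(measured = measured,
                                       estimated = estimated),
       correlation = stats::cor(measured, estimated),
       rmse = sqrt(sum(res^2) / n))
}

#' Serialize a fitted model to JSON
#'
#' Writes everything needed to reload a prediction-capable model bit-exactly:
#' variables, per-term knots and spline values, smoothing parameters, edf,
#' p-values, intercept, residuals and summary statistics. Doubles are
#' written at full precision.
#'
#' @param fit A `ferm_gam`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
gam_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ferm_gam"))
  payload <- list(
    container = "ferm_gam", version = 1L,
    intercept = fit$intercept, variables = fit$variables,
    basis_dim = fit$basis_dim, n = fit$n,
    terms = lapply(unname(fit$terms), function(tm)
      tm[c("variable", "knots", "values", "edf", "lambda", "p_value")]),
    residuals = fit$residuals, fitted = fit$fitted, response = fit$response,
    sigma2 = fit$sigma2, gcv = fit$gcv, adj_r2 = fit$adj_r2,
    total_edf = fit$total_edf)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "string")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Reload a serialized model
#'
#' @param path Path to a JSON file written by [gam_to_json()], or the JSON
#'   string itself.
#' @return A `ferm_gam` whose predictions are identical to the original
#'   fit's.
#' @export
gam_from_json <- function(path) {
  looks_like_json <- grepl("^\\s*\\{", path)
  p <- if (!looks_like_json && file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(p$container) || p$container != "ferm_gam") {
    stopf("not a serialized ferm_gam model")
  }
  terms <- lapply(seq_len(nrow(p$terms)), function(i) {
    tm <- lapply(p$terms, function(col) if (is.list(col)) col[[i]] else col[i])
    tm$knots <- as.numeric(tm$knots)
    tm$values <- as.numeric(tm$values)
    tm$lambda <- as.numeric(tm$lambda) # "Inf" round-trips as string
    tm
  })
  names(terms) <- vapply(terms, `[[`, character(1), "variable")
  structure(list(intercept = p$intercept, terms = terms,
                 variables = p$variables, basis_dim = p$basis_dim, n = p$n,
                 response = p$response, fitted = p$fitted,
                 residuals = p$residuals, total_edf = p$total_edf,
                 sigma2 = p$sigma2, gcv = p$gcv, adj_r2 = p$adj_r2),
            class = "ferm_gam")
}
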