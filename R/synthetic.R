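#' Configuration for a synthetic fermentation batch
#'
#' Describes the sampling cadences, target final titre and noise levels of a
#' simulated batch glutamate fermentation. Defaults emulate a typical 5-L
#' fed-batch run: offline glutamate assays every 2 h, online instrument
#' records (CER, DO, OUR, pH, stirring speed, temperature) every 6 min, and a
#' final titre drawn uniformly between 75 and 85 g/L.
#'
#' @param duration_h Total batch duration in hours.
#' @param offline_interval_h Interval between offline glutamate assays (h).
#'   Must be a positive multiple of the online interval.
#' @param online_interval_min Interval between online records (minutes).
#' @param final_glutamate_range Length-2 numeric, g/L: the final titre is
#'   drawn uniformly from this range.
#' @param noise_sd_glutamate Standard deviation of the additive Gaussian
#'   measurement noise on offline glutamate assays (g/L).
#' @param noise_sd_online Named numeric vector of per-channel additive noise
#'   standard deviations for `CER`, `DO`, `OUR`, `pH`, `SS`, `Temp` (in the
#'   channel's own units).
#' @param seed Integer seed; the only source of batch-to-batch variation.
#'
#' @return An object of class `batch_config`.
#' @export
batch_config <- function(duration_h = 30,
                         offline_interval_h = 2,
                         online_interval_min = 6,
                         final_glutamate_range = c(75, 85),
                         noise_sd_glutamate = 1.5,
                         noise_sd_online = c(CER = 2.5, DO = 1.2, OUR = 2.5,
                                             pH = 0.02, SS = 8, Temp = 0.03),
                         seed = 1L) {
  if (!is_number(duration_h) || duration_h <= 0) {
    stopf("duration_h must be a positive number, got %s", format(duration_h))
  }
  if (!is_number(offline_interval_h) || offline_interval_h <= 0) {
    stopf("offline_interval_h must be a positive number")
  }
  if (!is_number(online_interval_min) || online_interval_min <= 0) {
    stopf("online_interval_min must be a positive number")
  }
  ratio <- offline_interval_h / (online_interval_min / 60)
  if (abs(ratio - round(ratio)) > 1e-8 || round(ratio) < 1) {
    stopf(paste0("invalid cadence: offline_interval_h (%g h) is not a ",
                 "positive multiple of the online interval (%g min)"),
          offline_interval_h, online_interval_min)
  }
  if (length(final_glutamate_range) != 2 ||
      !all(is.finite(final_glutamate_range)) ||
      final_glutamate_range[1] >= final_glutamate_range[2]) {
    stopf("final_glutamate_range must be an increasing numeric pair")
  }
  missing_sd <- setdiff(ONLINE_VARS, names(noise_sd_online))
  if (length(missing_sd)) {
    stopf("noise_sd_online lacks channels: %s",
          paste(missing_sd, collapse = ", "))
  }
  structure(list(duration_h = duration_h,
                 offline_interval_h = offline_interval_h,
                 online_interval_min = online_interval_min,
                 final_glutamate_range = as.numeric(final_glutamate_range),
                 noise_sd_glutamate = noise_sd_glutamate,
                 noise_sd_online = noise_sd_online[ONLINE_VARS],
                 seed = as.integer(seed)),
            class = "batch_config")
}

#' Read a batch configuration from a YAML or JSON file
#'
#' @param path File path; `.yaml`/`.yml` parsed with the yaml package,
#'   anything else with jsonlite. Fields not present fall back to
#'   [batch_config()] defaults.
#' @return A `batch_config`.
#' @export
batch_config_from_file <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(batch_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stopf("unknown config fields: %s", paste(extra, collapse = ", "))
  if (!is.null(cfg$noise_sd_online)) {
    nso <- unlist(cfg$noise_sd_online)
    if (is.null(names(nso)) && length(nso) == length(ONLINE_VARS)) {
      names(nso) <- ONLINE_VARS # positional form, documented column order
    }
    cfg$noise_sd_online <- nso
  }
  do.call(batch_config, cfg)
}

#' Specification of an injected process fault
#'
#' @param kind `"stirring_drop"` (agitation failure: stirring collapses below
#'   300 rpm, DO falls to near zero, CER and OUR below 20 mol/m3/h) or
#'   `"nitrogen_substitution"` (NaOH used in place of ammonia water: CER and
#'   OUR depressed while pH, DO, temperature and stirring stay in their
#'   normal bands).
#' @param start_h,end_h Fault window in hours, `0 <= start_h < end_h`.
#' @param severity Fraction in (0, 1]: the in-window glutamate accumulation
#'   rate is multiplied by `1 - severity`; for `nitrogen_substitution` it also
#'   scales how far CER/OUR are depressed.
#' @return An object of class `fault_spec`.
#' @export
fault_spec <- function(kind, start_h, end_h, severity = 1) {
  kinds <- c("stirring_drop", "nitrogen_substitution")
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% kinds)) {
    stopf("unknown fault kind '%s' (expected one of: %s)",
          paste(kind, collapse = ","), paste(kinds, collapse = ", "))
  }
  if (!is_number(start_h) || !is_number(end_h) || start_h < 0 || start_h >= end_h) {
    stopf("fault window must satisfy 0 <= start_h < end_h")
  }
  if (!is_number(severity) || severity <= 0 || severity > 1) {
    stopf("severity must lie in (0, 1]")
  }
  structure(list(kind = kind, start_h = start_h, end_h = end_h,
                 severity = severity),
            class = "fault_spec")
}

# Smooth (noise-free) channel trajectories and titre curve for one batch,
# given the batch-level random effects in `pars`. Returns vectorised
# functions of time.
#
# DO follows a batch-specific controlled setpoint trajectory (runs are
# operated at different oxygen levels), deliberately decorrelated from the
# gas-exchange pulse, so the covariate effects on the titre are identifiable
# from a handful of pooled batches.
batch_truth <- function(pars, duration_h) {
  pulse <- function(t, tp) ifelse(t <= 0, 0, (t / tp)^3 * exp(3 * (1 - t / tp)))
  cer_s <- function(t) {
    40 + 12 * exp(-t / 1.5) + pars$cer_amp * pulse(t, pars$tp) +
      7 * sin(2 * pi * (t + pars$cer_phase) / pars$cer_period)
  }
  our_s <- function(t) {
    # OUR tracks the gas-exchange pulse ("similar trend" to CER) but carries
    # its own respiratory fluctuations, so the two channels are correlated
    # without being proportional
    base <- 40 + 12 * exp(-t / 1.5) + pars$cer_amp * pulse(t, pars$tp)
    pars$our_factor * base +
      6 * sin(2 * pi * (t + pars$our_phase) / pars$our_period)
  }
  do_s <- function(t) {
    # DO sags from its resting level toward ~10-15% while oxygen demand
    # peaks (the dip is synchronized with the batch's own CER pulse), with a
    # small slow drift from imperfect setpoint control
    pars$do_base - (pars$do_base - pars$do_dip) * pulse(t, pars$tp_do) +
      2 * sin(2 * pi * (t + pars$do_phase) / pars$do_period)
  }
  ss_s <- function(t) {
    480 + 2.2 * (cer_s(t) - 40) - 1.5 * (do_s(t) - 32) + pars$ss_shift
  }
  ph_s <- function(t) 7.1 + 0.04 * sin(2 * pi * t / 18) + pars$ph_shift
  temp_s <- function(t) 32.1 + pars$temp_shift + 0.06 * sin(2 * pi * t / 23)

  # Saturating (Monod-type) gas-exchange contributions to the titre:
  # production is limited by oxygen availability and metabolic activity when
  # they are low and saturates across the normal operating range, so healthy
  # batches differ little through these terms at any given time, while the
  # mid-run DO sag carries every batch through the steep low-oxygen region
  # the monitoring model must learn.
  cov_part <- function(t) {
    do_ <- do_s(t); cer_ <- cer_s(t); our_ <- our_s(t)
    40 * do_ / (12 + do_) + 26 * cer_ / (35 + cer_) + 14 * our_ / (35 + our_)
  }
  # The batch-random part of the titre: a common logistic time course plus a
  # whole-curve offset emerging with growth (inoculum-to-inoculum quality),
  # which carries the batch-to-batch spread of final titres. The offset is
  # deliberately not a function of any online channel: it is the honest
  # unexplained batch effect a prediction band has to cover.
  l <- function(t) stats::plogis((t - pars$tm) / pars$shape)
  logistic01 <- function(t) (l(t) - l(0)) / (l(duration_h) - l(0))
  c0 <- cov_part(0)
  amp <- pars$final_mid - (cov_part(duration_h) - c0)
  offset <- pars$final - pars$final_mid
  glut <- function(t) {
    pmax(0, amp * logistic01(t) + offset * sqrt(logistic01(t)) +
           cov_part(t) - c0)
  }

  list(glutamate = glut, CER = cer_s, DO = do_s, OUR = our_s,
       pH = ph_s, SS = ss_s, Temp = temp_s)
}

#' Simulate one normal fermentation batch
#'
#' Generates a batch whose signals follow the stylised profiles of a healthy
#' glutamate fermentation: CER rises from ~50 to a peak near 170 mol/m3/h
#' within the first 4-7 h and decays back towards ~40; OUR tracks CER up to a
#' batch-specific factor near 1; DO mirrors the oxygen demand within ~10-55%;
#' stirring speed follows demand within 400-900 rpm; pH is held near 7.1 and
#' temperature near 32.1 degC. The titre follows a saturating logistic time
#' course, plus modest nonlinear contributions of the gas-exchange channels,
#' reaching a batch-random final value in `final_glutamate_range`. All
#' batch-to-batch variation is driven by `config$seed`.
#'
#' @param config A [batch_config()].
#' @param batch_id Identifier stored on the batch.
#' @return A `fermentation_batch`: list with `batch_id`, `offline`
#'   (data.frame `time_h`, `glutamate`), `online` (data.frame `time_h`,
#'   `CER`, `DO`, `OUR`, `pH`, `SS`, `Temp`) and `faults` (empty list).
#' @export
simulate_normal_batch <- function(config = batch_config(),
                                  batch_id = sprintf("batch_s%d", config$seed)) {
  stopifnot(inherits(config, "batch_config"))
  dt_online <- config$online_interval_min / 60
  t_online <- seq(0, config$duration_h, by = dt_online)
  t_offline <- seq(0, config$duration_h, by = config$offline_interval_h)
  # offline assays must coincide with online records
  if (!all(vapply(t_offline, function(t) min(abs(t_online - t)) < 1e-8, TRUE))) {
    stopf("invalid cadence: offline times are not on the online grid")
  }

  with_seed(config$seed, {
    fg <- config$final_glutamate_range
    # final titre: bell-shaped within the configured envelope (batch
    # outcomes cluster around the typical run)
    pars <- list(final = fg[1] + (fg[2] - fg[1]) * stats::rbeta(1, 3, 3),
                 final_mid = mean(fg),
                 tm = stats::runif(1, 12.2, 12.8) * config$duration_h / 30,
                 shape = stats::runif(1, 3.5, 3.9),
                 cer_amp = stats::runif(1, 120, 130),
                 tp = stats::runif(1, 5.2, 5.8),
                 cer_phase = stats::runif(1, 0, 10),
                 cer_period = stats::runif(1, 7, 11),
                 our_factor = stats::runif(1, 0.97, 1.03),
                 our_phase = stats::runif(1, 0, 12),
                 our_period = stats::runif(1, 8, 12),
                 do_base = stats::runif(1, 33, 37),
                 do_dip = stats::runif(1, 11, 14),
                 do_phase = stats::runif(1, 0, 24),
                 do_period = stats::runif(1, 14, 26),
                 ss_shift = stats::runif(1, -30, 30),
                 ph_shift = stats::runif(1, -0.03, 0.03),
                 temp_shift = stats::runif(1, -0.12, 0.12))
    # DO sag timing tracks, but is not locked to, the gas-exchange pulse
    pars$tp_do <- pars$tp + stats::runif(1, -0.6, 0.6)
    truth <- batch_truth(pars, config$duration_h)

    offline <- data.frame(
      time_h = t_offline,
      glutamate = pmax(0, truth$glutamate(t_offline) +
                          stats::rnorm(length(t_offline), 0,
                                       config$noise_sd_glutamate)))

    sd <- config$noise_sd_online
    n <- length(t_online)
    online <- data.frame(
      time_h = t_online,
      CER = pmax(0.5, truth$CER(t_online) + stats::rnorm(n, 0, sd[["CER"]])),
      DO = pmin(59, pmax(0.5, truth$DO(t_online) + stats::rnorm(n, 0, sd[["DO"]]))),
      OUR = pmax(0.5, truth$OUR(t_online) + stats::rnorm(n, 0, sd[["OUR"]])),
      pH = pmin(7.28, pmax(6.92, truth$pH(t_online) + stats::rnorm(n, 0, sd[["pH"]]))),
      SS = pmin(898, pmax(402, truth$SS(t_online) + stats::rnorm(n, 0, sd[["SS"]]))),
      Temp = pmin(32.38, pmax(31.82,
                              truth$Temp(t_online) + stats::rnorm(n, 0, sd[["Temp"]]))))

    structure(list(batch_id = batch_id, offline = offline, online = online,
                   faults = list()),
              class = "fermentation_batch")
  })
}

#' @export
print.fermentation_batch <- function(x, ...) {
  cat(sprintf("<fermentation_batch '%s': %d offline assays, %d online records, %d fault(s)>\n",
              x$batch_id, nrow(x$offline), nrow(x$online), length(x$faults)))
  invisible(x)
}

#' Inject a process fault into a batch
#'
#' Deterministically rewrites the signals inside the fault window; every
#' sample outside the window is left bit-identical to the input batch, so the
#' transform is idempotent off-window and the original object is not
#' modified.
#'
#' For `stirring_drop`, in-window stirring speed collapses below 300 rpm, DO
#' to near 0%, and CER/OUR below 20 mol/m3/h (an agitation failure starving
#' the culture of oxygen). For `nitrogen_substitution`, in-window CER and OUR
#' are depressed by a factor `1 - 0.75 * severity` while pH, DO, temperature
#' and stirring are untouched (the pH controller masks the missing nitrogen
#' source). In both cases the offline titre increments inside the window are
#' scaled by `1 - severity`.
#'
#' @param batch A `fermentation_batch`.
#' @param fault A [fault_spec()] whose window lies inside the batch duration.
#' @return A new `fermentation_batch` with the fault applied and appended to
#'   `$faults`.
#' @export
inject_fault <- function(batch, fault) {
  stopifnot(inherits(batch, "fermentation_batch"))
  if (!inherits(fault, "fault_spec")) {
    fault <- do.call(fault_spec, as.list(fault))
  }
  duration <- max(batch$online$time_h)
  if (fault$end_h > duration + 1e-8) {
    stopf("fault window [%g, %g] exceeds batch duration %g h",
          fault$start_h, fault$end_h, duration)
  }
  out <- batch
  tol <- 1e-9
  t_on <- out$online$time_h
  win <- t_on >= fault$start_h - tol & t_on <= fault$end_h + tol

  if (fault$kind == "stirring_drop") {
    out$online$SS[win] <- 220 + 0.08 * out$online$SS[win]
    out$online$DO[win] <- 0.04 * out$online$DO[win]
    out$online$CER[win] <- 10 + 0.035 * out$online$CER[win]
    out$online$OUR[win] <- 10 + 0.035 * out$online$OUR[win]
  } else { # nitrogen_substitution
    depress <- 1 - 0.82 * fault$severity
    out$online$CER[win] <- depress * out$online$CER[win]
    out$online$OUR[win] <- depress * out$online$OUR[win]
  }

  # stalled accumulation: scale in-window titre increments by (1 - severity),
  # anchored at the last assay at or before the fault start
  t_off <- out$offline$time_h
  anchor_idx <- max(which(t_off <= fault$start_h + tol))
  g0 <- batch$offline$glutamate[anchor_idx]
  win_off <- t_off > fault$start_h + tol & t_off <= fault$end_h + tol
  out$offline$glutamate[win_off] <-
    pmax(0, g0 + (1 - fault$severity) * (batch$offline$glutamate[win_off] - g0))

  out$faults <- c(out$faults, list(fault))
  out
}

#' Generate a reproducible study set of normal and faulted batches
#'
#' @param n_normal Number of normal batches (>= 2).
#' @param fault_specs List of [fault_spec()]s; one additional faulted batch is
#'   generated per spec.
#' @param base_seed Integer; per-batch sub-seeds are derived from it
#'   deterministically, so the same arguments always give the same set.
#' @param config Template [batch_config()] (its `seed` is overridden
#'   per batch).
#' @return List of `fermentation_batch` with distinct `batch_id`s; normal
#'   batches first.
#' @export
make_study_set <- function(n_normal, fault_specs = list(), base_seed = 1L,
                           config = batch_config()) {
  if (!is_count(n_normal) || n_normal < 2) stopf("n_normal must be >= 2")
  normals <- lapply(seq_len(n_normal), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, i)
    simulate_normal_batch(cfg, batch_id = sprintf("normal_%02d", i))
  })
  faulted <- lapply(seq_along(fault_specs), function(j) {
    cfg <- config
    cfg$seed <- derive_seed(base_seed, n_normal + j)
    b <- simulate_normal_batch(cfg, batch_id = sprintf("fault_%02d_%s", j,
                                                       fault_specs[[j]]$kind))
    inject_fault(b, fault_specs[[j]])
  })
  c(normals, faulted)
}

#' Simulate a training table with known additive structure
#'
#' Benchmark generator for model-selection and smooth-recovery studies: the
#' response depends on `T`, `DO`, `OUR` and `CER` through known nonlinear
#' functions, while `SS`, `pH` and `Temp` are pure noise covariates. All
#' covariates are drawn independently over their realistic operating ranges,
#' so, unlike pooled fermentation batches, the design carries no concurvity.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param noise_sd Residual standard deviation, g/L.
#' @return A data.frame usable as a training table, with attribute `"truth"`:
#'   a named list of the true component functions (centred arbitrarily).
#' @export
simulate_additive_table <- function(n = 80, seed = 1L, noise_sd = 1.5) {
  truth <- list(
    T = function(x) 45 * stats::plogis((x - 12) / 4),
    DO = function(x) { u <- (45 - x) / 25; 8 * (u - 0.2 * u^2) },
    OUR = function(x) 5 * log(x / 45),
    CER = function(x) 10 * (sqrt(x / 40) - 1))
  with_seed(seed, {
    tab <- data.frame(
      batch_id = "sim",
      T = stats::runif(n, 0, 30),
      DO = stats::runif(n, 10, 55),
      OUR = stats::runif(n, 40, 170),
      CER = stats::runif(n, 40, 170),
      SS = stats::runif(n, 400, 900),
      pH = stats::runif(n, 6.9, 7.3),
      Temp = stats::runif(n, 31.8, 32.4))
    tab$glutamate <- 20 + truth$T(tab$T) + truth$DO(tab$DO) +
      truth$OUR(tab$OUR) + truth$CER(tab$CER) + stats::rnorm(n, 0, noise_sd)
    attr(tab, "truth") <- truth
    tab
  })
}
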