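#' Estimate glutamate production from an online record stream
#'
#' Evaluates the fitted additive model at every online record (fermentation
#' time taken from the stream's `time_h`), giving the online soft-sensor
#' estimate of production that the fault monitor compares against the band.
#' Estimates are clamped below at 0 g/L.
#'
#' @param fit A `ferm_gam`.
#' @param online A `fermentation_batch` or its `$online` data.frame
#'   (`time_h` plus the online channels the model uses).
#' @return Data.frame with `time_h` and `estimate` (g/L), one row per
#'   record.
#' @export
estimate_online <- function(fit, online) {
  stopifnot(inherits(fit, "ferm_gam"))
  if (inherits(online, "fermentation_batch")) online <- online$online
  nd <- online
  nd$T <- online$time_h
  missing_v <- setdiff(fit$variables, names(nd))
  if (length(missing_v)) {
    stopf("online stream lacks model variable(s): %s",
          paste(missing_v, collapse = ", "))
  }
  data.frame(time_h = online$time_h,
             estimate = pmax(0, predict(fit, nd)))
}

#' Detect fault intervals from estimates and a prediction band
#'
#' A time point is out-of-band iff the estimate lies below the lower or
#' above the upper band edge (band linearly interpolated at the estimate
#' times). A fault event starts at the first of at least `debounce`
#' consecutive out-of-band points and ends at the first of at least
#' `debounce` consecutive in-band points (when the estimate returns into the
#' band); an event still open when the stream ends is reported with
#' `end_h = NA`.
#'
#' @param estimates Data.frame from [estimate_online()] (`time_h`,
#'   `estimate`); times must lie inside the band grid range.
#' @param band A `bootstrap_band`.
#' @param debounce Minimal run length of out-of-band (in-band) points to
#'   open (close) an event; default 1 flags immediately.
#' @param batch_id Optional identifier carried on the report.
#' @return An object of class `fault_report`: `batch_id`, `records`
#'   (per-point `time_h`, `estimate`, `lower`, `upper`, `in_band`) and
#'   `events` (list with `start_h`, `end_h`, `peak_excursion`, `open`).
#' @export
detect_faults <- function(estimates, band, debounce = 1, batch_id = NULL) {
  stopifnot(inherits(band, "bootstrap_band"))
  if (!nrow(estimates)) stopf("empty estimate stream")
  if (!is_count(debounce) || debounce < 1) stopf("debounce must be >= 1")
  edges <- interpolate_band(band, estimates$time_h)
  records <- data.frame(time_h = estimates$time_h,
                        estimate = estimates$estimate,
                        lower = edges$lower, upper = edges$upper)
  records$in_band <- records$estimate >= records$lower - 1e-9 &
    records$estimate <= records$upper + 1e-9
  excess <- pmax(records$lower - records$estimate,
                 records$estimate - records$upper, 0)

  runs <- rle(!records$in_band)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  events <- list()
  open_start <- NA_integer_
  for (r in seq_along(runs$lengths)) {
    if (runs$values[r]) { # out-of-band run
      if (is.na(open_start) && runs$lengths[r] >= debounce) {
        open_start <- starts[r]
      }
    } else if (!is.na(open_start) && runs$lengths[r] >= debounce) {
      idx <- open_start:(starts[r] - 1L)
      events[[length(events) + 1L]] <-
        list(start_h = records$time_h[open_start],
             end_h = records$time_h[starts[r]],
             peak_excursion = max(excess[idx]), open = FALSE)
      open_start <- NA_integer_
    }
  }
  if (!is.na(open_start)) {
    idx <- open_start:nrow(records)
    events[[length(events) + 1L]] <-
      list(start_h = records$time_h[open_start], end_h = NA_real_,
           peak_excursion = max(excess[idx]), open = TRUE)
  }
  structure(list(batch_id = batch_id, records = records, events = events),
            class = "fault_report")
}

#' @export
print.fault_report <- function(x, ...) {
  cat(summarize_report(x)$text, sep = "\n")
  invisible(x)
}

#' Summarize a fault report
#'
#' @param report A `fault_report`.
#' @return List with `text` (character vector: one line per event, in
#'   chronological order, plus totals) and `json` (machine-readable twin as
#'   a JSON string).
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "fault_report"))
  id <- if (is.null(report$batch_id)) "stream" else report$batch_id
  n_out <- sum(!report$records$in_band)
  if (!length(report$events)) {
    text <- c(sprintf("%s: no faults detected (%d/%d points out of band)",
                      id, n_out, nrow(report$records)))
  } else {
    lines <- vapply(report$events, function(ev) {
      if (ev$open) {
        sprintf("fault from %.2f h (unresolved at stream end), peak excursion %.2f g/L",
                ev$start_h, ev$peak_excursion)
      } else {
        sprintf("fault from %.2f h to %.2f h (duration %.2f h), peak excursion %.2f g/L",
                ev$start_h, ev$end_h, ev$end_h - ev$start_h,
                ev$peak_excursion)
      }
    }, character(1))
    text <- c(sprintf("%s: %d fault event(s), %d/%d points out of band",
                      id, length(report$events), n_out,
                      nrow(report$records)),
              lines)
  }
  events_js <- lapply(report$events, function(ev) {
    ev$duration_h <- if (ev$open) NA_real_ else ev$end_h - ev$start_h
    ev
  })
  json <- jsonlite::toJSON(list(batch_id = id, n_events = length(report$events),
                                n_out_of_band = n_out,
                                n_points = nrow(report$records),
                                events = events_js),
                           auto_unbox = TRUE, digits = NA, na = "null")
  list(text = text, json = as.character(json))
}
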