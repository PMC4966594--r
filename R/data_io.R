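#' Write a fermentation batch to CSV files
#'
#' Writes `<batch_id>_offline.csv` (columns `time_h`, `glutamate`) and
#' `<batch_id>_online.csv` (columns `time_h`, `CER`, `DO`, `OUR`, `pH`, `SS`,
#' `Temp`) into `dir`. Values are written at full precision so a write/read
#' round trip reproduces the batch. Fault annotations are in-memory metadata
#' and are not persisted.
#'
#' @param batch A `fermentation_batch`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_batch_csv <- function(batch, dir) {
  stopifnot(inherits(batch, "fermentation_batch"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(offline = file.path(dir, paste0(batch$batch_id, "_offline.csv")),
             online = file.path(dir, paste0(batch$batch_id, "_online.csv")))
  fmt <- function(d) {
    d[] <- lapply(d, function(col) format(col, digits = 17, trim = TRUE,
                                          scientific = FALSE))
    d
  }
  utils::write.csv(fmt(batch$offline), paths[["offline"]],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(batch$online), paths[["online"]],
                   row.names = FALSE, quote = FALSE)
  invisible(paths)
}

read_series_csv <- function(path, required, what) {
  if (!file.exists(path)) stopf("%s file not found: %s", what, path)
  d <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stopf("%s file '%s' lacks required column(s): %s",
          what, basename(path), paste(missing, collapse = ", "))
  }
  d <- d[required]
  for (nm in required) {
    v <- suppressWarnings(as.numeric(d[[nm]]))
    bad <- which(is.na(v) & !is.na(d[[nm]]))
    if (any(is.na(d[[nm]])) || length(bad)) {
      row <- if (length(bad)) bad[1] else which(is.na(d[[nm]]))[1]
      stopf("%s file '%s': non-numeric value in column '%s' (row %d)",
            what, basename(path), nm, row)
    }
    d[[nm]] <- v
  }
  if (is.unsorted(d$time_h, strictly = TRUE)) {
    stopf("%s file '%s': column 'time_h' must be strictly increasing",
          what, basename(path))
  }
  d
}

#' Read a fermentation batch from CSV files
#'
#' Expects the pair of files written by [write_batch_csv()] under
#' `dir`. Column presence, numeric parsing and strictly increasing time are
#' validated; coverage of offline times by the online grid is checked later,
#' at alignment.
#'
#' @param dir Directory containing `<batch_id>_offline.csv` and
#'   `<batch_id>_online.csv`.
#' @param batch_id Batch identifier (file-name prefix).
#' @return A `fermentation_batch` (with no fault annotations).
#' @export
read_batch_csv <- function(dir, batch_id) {
  offline <- read_series_csv(file.path(dir, paste0(batch_id, "_offline.csv")),
                             c("time_h", "glutamate"), "offline")
  online <- read_series_csv(file.path(dir, paste0(batch_id, "_online.csv")),
                            c("time_h", ONLINE_VARS), "online")
  structure(list(batch_id = batch_id, offline = offline, online = online,
                 faults = list()),
            class = "fermentation_batch")
}

#' Align offline assays with online records into a training table
#'
#' Pairs each offline glutamate assay with the nearest-in-time online record
#' of the same batch (tolerance +/- 3 min, half the default online cadence)
#' and pools the rows across batches. The result is the table the additive
#' model is fitted on: one row per offline measurement with columns
#' `batch_id`, `T` (fermentation time, h), `DO`, `OUR`, `CER`, `SS`, `pH`,
#' `Temp` and `glutamate`. Rows are sorted by `batch_id` then time, so the
#' output does not depend on the order batches are supplied in.
#'
#' @param batches List of `fermentation_batch` (or a single batch).
#' @param tolerance_min Maximal offline/online time gap, minutes.
#' @return A data.frame training table.
#' @export
align_offline_online <- function(batches, tolerance_min = 3) {
  if (inherits(batches, "fermentation_batch")) batches <- list(batches)
  if (!length(batches)) stopf("no batches supplied")
  rows <- lapply(batches, function(b) {
    stopifnot(inherits(b, "fermentation_batch"))
    idx <- vapply(b$offline$time_h, function(t) {
      gaps <- abs(b$online$time_h - t)
      j <- which.min(gaps)
      if (gaps[j] > tolerance_min / 60 + 1e-9) {
        stopf("batch '%s': no online record within %g min of offline time %g h",
              b$batch_id, tolerance_min, t)
      }
      j
    }, integer(1))
    data.frame(batch_id = b$batch_id,
               T = b$offline$time_h,
               DO = b$online$DO[idx],
               OUR = b$online$OUR[idx],
               CER = b$online$CER[idx],
               SS = b$online$SS[idx],
               pH = b$online$pH[idx],
               Temp = b$online$Temp[idx],
               glutamate = b$offline$glutamate)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$batch_id, tab$T), , drop = FALSE]
  rownames(tab) <- NULL
  if (anyNA(tab)) stopf("training table contains missing values")
  tab
}
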