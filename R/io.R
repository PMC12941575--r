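FORMAT_VERSION <- "1.0"

#' Write a recording as CSV plus JSON sidecar
#'
#' The CSV holds the signal matrix (header row = channel names, one row per
#' time step, values at full double precision); the sidecar holds subject id,
#' label, sampling rate, channel order, and the event log if present. Both
#' writers are deterministic, so identical recordings produce identical
#' bytes.
#'
#' @param recording a [gait_recording()] with at least one channel.
#' @param csv_path,sidecar_path output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_recording <- function(recording, csv_path, sidecar_path) {
  if (ncol(recording$data) < 1L) {
    stop("cannot write a recording with no channels", call. = FALSE)
  }
  dt <- data.table::as.data.table(recording$data)
  data.table::setnames(dt, recording$channel_names)
  data.table::fwrite(dt, csv_path)
  meta <- list(format_version = FORMAT_VERSION,
               subject_id = recording$subject_id, label = recording$label,
               sample_rate_hz = recording$sample_rate_hz,
               channel_names = as.list(recording$channel_names))
  if (!is.null(recording$event_log)) {
    meta$event_log <- recording$event_log
  }
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv_path, sidecar_path))
}

#' Read a recording from CSV plus JSON sidecar
#'
#' @param csv_path CSV with a header row of channel names and numeric cells.
#' @param sidecar_path JSON sidecar with `subject_id`, `label` (one of
#'   `"HEALTHY"`/`"PD"`), and `sample_rate_hz`.
#' @return A [gait_recording()].
#' @export
read_recording <- function(csv_path, sidecar_path) {
  meta <- tryCatch(jsonlite::read_json(sidecar_path, simplifyVector = TRUE),
                   error = function(e) {
                     stop("cannot parse sidecar ", sidecar_path, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
  for (f in c("subject_id", "label", "sample_rate_hz")) {
    if (is.null(meta[[f]])) {
      stop("sidecar ", sidecar_path, " is missing field '", f, "'",
           call. = FALSE)
    }
  }
  if (!meta$label %in% GAIT_LABELS) {
    stop("sidecar ", sidecar_path, ": label '", meta$label,
         "' is outside the two-class set (HEALTHY, PD)", call. = FALSE)
  }
  if (meta$sample_rate_hz <= 0) {
    stop("sidecar ", sidecar_path, ": sample_rate_hz must be positive",
         call. = FALSE)
  }
  nfields <- utils::count.fields(csv_path, sep = ",", quote = "\"")
  if (length(nfields) < 2L) {
    stop("malformed CSV ", csv_path, ": need a header row and at least one ",
         "data row", call. = FALSE)
  }
  bad_rows <- which(nfields != nfields[1])
  if (length(bad_rows)) {
    stop("malformed CSV ", csv_path, ": row ", bad_rows[1], " has ",
         nfields[bad_rows[1]], " fields, expected ", nfields[1],
         call. = FALSE)
  }
  dt <- tryCatch(
    suppressWarnings(data.table::fread(csv_path, header = TRUE,
                                       showProgress = FALSE)),
    error = function(e) {
      stop("malformed CSV ", csv_path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  for (j in seq_along(dt)) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) | !grepl(
        "^[-+0-9.eE ]*$", as.character(col)))
      row <- if (length(bad)) bad[1] else 1L
      stop("non-numeric cell in ", csv_path, ", column '", names(dt)[j],
           "', data row ", row, call. = FALSE)
    }
  }
  data <- as.matrix(dt)
  gait_recording(meta$subject_id, meta$label, meta$sample_rate_hz, data,
                 channel_names = names(dt),
                 event_log = meta$event_log)
}

#' Write a cohort to a directory with a manifest
#'
#' One CSV + JSON sidecar pair per recording plus a `manifest.json` listing
#' every entry and the per-label counts.
#'
#' @param recordings list of [gait_recording()] objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(recordings, function(rec) {
    csv <- file.path(dir, paste0(rec$subject_id, ".csv"))
    sc <- file.path(dir, paste0(rec$subject_id, ".json"))
    write_recording(rec, csv, sc)
    list(csv_path = basename(csv), sidecar_path = basename(sc),
         subject_id = rec$subject_id, label = rec$label)
  })
  labels <- vapply(recordings, function(r) r$label, character(1))
  manifest <- list(format_version = FORMAT_VERSION, entries = entries,
                   counts = as.list(table(factor(labels,
                                                 levels = GAIT_LABELS))))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return List of [gait_recording()] objects in manifest order.
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    stop("no manifest.json in ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(manifest$entries, function(e) {
    read_recording(file.path(dir, e$csv_path), file.path(dir, e$sidecar_path))
  })
}

#' Serialize an evaluation report to JSON
#'
#' The document carries every metric, the confusion counts, ROC points, the
#' per-epoch learning curves, the configuration fingerprint, and seeds, under
#' a versioned schema, so a written report reproduces the evaluation exactly
#' on re-reading.
#'
#' @param report an [compute_metrics()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  doc <- list(
    schema_version = FORMAT_VERSION,
    accuracy = report$accuracy, sensitivity = report$sensitivity,
    specificity = report$specificity, auc = report$auc,
    threshold = report$threshold, confusion = report$confusion,
    roc_points = report$roc_points,
    history = report$history,
    config_fingerprint = report$config_fingerprint, seeds = report$seeds)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#'
#' @param path JSON report path.
#' @return An `evaluation_report`.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  roc <- as.data.frame(doc$roc_points)
  roc[] <- lapply(roc, as.numeric)
  structure(
    list(accuracy = as.numeric(doc$accuracy),
         sensitivity = as.numeric(doc$sensitivity),
         specificity = as.numeric(doc$specificity),
         auc = as.numeric(doc$auc),
         confusion = lapply(as.list(doc$confusion), as.integer),
         roc_points = roc,
         threshold = as.numeric(doc$threshold),
         history = if (is.null(doc$history)) NULL else
           as.data.frame(doc$history),
         config_fingerprint = doc$config_fingerprint, seeds = doc$seeds),
    class = "evaluation_report")
}
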