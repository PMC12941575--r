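#' Construct a gait recording
#'
#' A `gait_recording` holds one subject's continuous multichannel signal
#' together with its class label and sampling rate. The simulator additionally
#' attaches a ground-truth event log of stride-onset times, which downstream
#' variability diagnostics use as an exact oracle.
#'
#' @param subject_id single string identifying the subject.
#' @param label `"HEALTHY"` or `"PD"`.
#' @param sample_rate_hz sampling rate in samples per second (> 0).
#' @param data numeric matrix, rows = time steps, columns = channels.
#' @param channel_names character vector naming the columns of `data`;
#'   defaults to the column names of `data`.
#' @param event_log optional numeric vector of stride-onset times in seconds.
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(subject_id, label, sample_rate_hz, data,
                           channel_names = colnames(data), event_log = NULL) {
  label <- match_label(label)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric matrix", call. = FALSE)
  }
  if (nrow(data) < 1L) stop("data must have at least one row", call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- sprintf("ch%02d", seq_len(ncol(data)))
  }
  if (length(channel_names) != ncol(data)) {
    stop("channel_names length must equal ncol(data)", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  }
  colnames(data) <- channel_names
  structure(
    list(subject_id = as.character(subject_id), label = label,
         sample_rate_hz = as.numeric(sample_rate_hz),
         channel_names = as.character(channel_names), data = data,
         event_log = event_log),
    class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> %s [%s] %d x %d @ %g Hz (%.1f s)%s\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data),
              x$sample_rate_hz, nrow(x$data) / x$sample_rate_hz,
              if (is.null(x$event_log)) "" else
                sprintf(", %d stride events", length(x$event_log))))
  invisible(x)
}

#' Construct a fixed-length gait segment
#'
#' Segments are the unit of classification: fixed-length windows cut from a
#' preprocessed recording (125 samples = 5 s at 25 Hz by default). Provenance
#' distinguishes windows cut from real signal (`"ORIGINAL"`) from time-warped
#' variants (`"SYNTHETIC"`), which must carry a `parent_id`.
#'
#' @param data numeric matrix, rows = time steps, columns = channels.
#' @param label `"HEALTHY"` or `"PD"`, inherited from the source subject.
#' @param subject_id id of the originating subject.
#' @param segment_index 1-based window index within the source recording.
#' @param provenance `"ORIGINAL"` or `"SYNTHETIC"`.
#' @param parent_id id of the parent segment (required for synthetics).
#' @param id unique segment identifier; derived from subject and index when
#'   omitted.
#' @return An object of class `gait_segment`.
#' @export
gait_segment <- function(data, label, subject_id, segment_index,
                         provenance = c("ORIGINAL", "SYNTHETIC"),
                         parent_id = NULL, id = NULL) {
  provenance <- match.arg(provenance)
  label <- match_label(label)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("segment data must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("segment data must be finite", call. = FALSE)
  }
  if (provenance == "SYNTHETIC" && is.null(parent_id)) {
    stop("SYNTHETIC segments must carry a parent_id", call. = FALSE)
  }
  if (is.null(id)) id <- sprintf("%s_s%03d", subject_id, segment_index)
  structure(
    list(data = data, label = label, subject_id = as.character(subject_id),
         segment_index = as.integer(segment_index), provenance = provenance,
         parent_id = parent_id, id = id),
    class = "gait_segment")
}

#' @export
print.gait_segment <- function(x, ...) {
  cat(sprintf("<gait_segment> %s [%s, %s] %d x %d%s\n", x$id, x$label,
              x$provenance, nrow(x$data), ncol(x$data),
              if (is.null(x$parent_id)) "" else paste0(" <- ", x$parent_id)))
  invisible(x)
}

segment_labels <- function(segments) {
  vapply(segments, function(s) s$label, character(1))
}

segment_provenance <- function(segments) {
  vapply(segments, function(s) s$provenance, character(1))
}

segment_ids <- function(segments) {
  vapply(segments, function(s) s$id, character(1))
}

# Stack a list of equally shaped segments into an L x C x N array.
segments_to_array <- function(segments) {
  dims <- vapply(segments, function(s) dim(s$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all segments must share the same shape", call. = FALSE)
  }
  array(unlist(lapply(segments, function(s) s$data), use.names = FALSE),
        dim = c(dims[1, 1], dims[2, 1], length(segments)))
}
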