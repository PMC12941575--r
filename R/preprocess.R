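#' Configure the signal-conditioning chain
#'
#' The chain applies, in fixed order: resampling to `target_rate_hz`,
#' Savitzky-Golay smoothing, Butterworth low-pass filtering, and per-channel
#' z-normalization, followed by fixed-length segmentation. Defaults follow
#' common gait-analysis practice: 25 Hz working rate, an 11-sample cubic
#' Savitzky-Golay window (0.44 s at 25 Hz, short enough to preserve gait
#' events), and a 4th-order 6 Hz low-pass, above the frequency band that
#' carries locomotor content.
#'
#' @param target_rate_hz working sampling rate after resampling.
#' @param sg_window odd Savitzky-Golay window length in samples.
#' @param sg_polyorder Savitzky-Golay polynomial order (< `sg_window`).
#' @param butter_order Butterworth filter order.
#' @param butter_cutoff_hz low-pass cutoff in Hz (< Nyquist at the target rate).
#' @param zero_phase if `TRUE` (default) the Butterworth filter is applied
#'   forward-backward, doubling attenuation but introducing no phase shift.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate_hz = 25, sg_window = 11,
                              sg_polyorder = 3, butter_order = 4,
                              butter_cutoff_hz = 6, zero_phase = TRUE) {
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder", call. = FALSE)
  }
  if (butter_cutoff_hz <= 0 || butter_cutoff_hz >= target_rate_hz / 2) {
    stop("butter_cutoff_hz must lie in (0, target_rate_hz / 2)", call. = FALSE)
  }
  structure(
    list(target_rate_hz = target_rate_hz, sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder),
         butter_order = as.integer(butter_order),
         butter_cutoff_hz = butter_cutoff_hz,
         zero_phase = isTRUE(zero_phase)),
    class = "preprocess_config")
}

#' Resample a recording to a uniform grid at a new rate
#'
#' Linear interpolation on a uniform time grid; the output has
#' `floor(T * target / native)` samples. The event log, which is expressed
#' in seconds, is carried through unchanged.
#'
#' @param recording a [gait_recording()].
#' @param target_rate_hz new sampling rate (> 0).
#' @return The resampled [gait_recording()].
#' @export
resample_recording <- function(recording, target_rate_hz) {
  if (target_rate_hz <= 0) stop("target_rate_hz must be positive", call. = FALSE)
  native <- recording$sample_rate_hz
  if (target_rate_hz > 4 * native) {
    warning("upsampling beyond 4x the native rate (", native, " -> ",
            target_rate_hz, " Hz)")
  }
  n_in <- nrow(recording$data)
  n_out <- floor(n_in * target_rate_hz / native)
  t_in <- (seq_len(n_in) - 1) / native
  t_out <- (seq_len(n_out) - 1) / target_rate_hz
  out <- apply(recording$data, 2, function(x) {
    approx(t_in, x, xout = t_out, rule = 2)$y
  })
  gait_recording(recording$subject_id, recording$label, target_rate_hz,
                 matrix(out, nrow = n_out), recording$channel_names,
                 recording$event_log)
}

#' Savitzky-Golay smoothing of every channel
#'
#' Local least-squares polynomial smoothing that removes sample-to-sample
#' jitter while reproducing any polynomial of degree up to `sg_polyorder`
#' exactly, so sharp but smooth gait events are preserved.
#'
#' @param recording a [gait_recording()].
#' @param config a [preprocess_config()].
#' @return The smoothed [gait_recording()].
#' @export
savitzky_golay <- function(recording, config = preprocess_config()) {
  if (config$sg_window > nrow(recording$data)) {
    stop("sg_window (", config$sg_window, ") longer than the signal (",
         nrow(recording$data), " samples)", call. = FALSE)
  }
  out <- apply(recording$data, 2, function(x) {
    signal::sgolayfilt(x, p = config$sg_polyorder, n = config$sg_window)
  })
  gait_recording(recording$subject_id, recording$label,
                 recording$sample_rate_hz,
                 matrix(out, nrow = nrow(recording$data)),
                 recording$channel_names, recording$event_log)
}

#' Butterworth low-pass filtering of every channel
#'
#' Channels are mean-centred before filtering (and the mean restored after)
#' so the DC level passes through exactly and start-up transients are kept
#' small. With `zero_phase` the filter runs forward and backward, squaring
#' the magnitude response (gain 0.5 at the cutoff) and cancelling phase.
#'
#' @param recording a [gait_recording()].
#' @param config a [preprocess_config()]; the cutoff must be below the
#'   recording's Nyquist frequency.
#' @return The filtered [gait_recording()].
#' @export
butterworth_lowpass <- function(recording, config = preprocess_config()) {
  nyq <- recording$sample_rate_hz / 2
  if (config$butter_cutoff_hz >= nyq) {
    stop("butter_cutoff_hz (", config$butter_cutoff_hz,
         ") must be below the Nyquist frequency (", nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(config$butter_order, config$butter_cutoff_hz / nyq,
                       type = "low")
  out <- apply(recording$data, 2, function(x) {
    mu <- mean(x)
    y <- if (config$zero_phase) signal::filtfilt(bf, x - mu) else
      as.numeric(signal::filter(bf, x - mu))
    y + mu
  })
  gait_recording(recording$subject_id, recording$label,
                 recording$sample_rate_hz,
                 matrix(out, nrow = nrow(recording$data)),
                 recording$channel_names, recording$event_log)
}

#' Normalize every channel to zero mean and unit variance
#'
#' Channels with (numerically) zero variance are mapped to all-zeros with a
#' warning rather than dividing by zero.
#'
#' @param recording a [gait_recording()] with at least 2 samples.
#' @return The normalized [gait_recording()].
#' @export
znormalize <- function(recording) {
  if (nrow(recording$data) < 2L) {
    stop("znormalize needs at least 2 samples", call. = FALSE)
  }
  out <- apply(recording$data, 2, function(x) {
    s <- sd(x)
    if (!is.finite(s) || s < 1e-12) {
      warning("zero-variance channel mapped to zeros")
      rep(0, length(x))
    } else {
      (x - mean(x)) / s
    }
  })
  gait_recording(recording$subject_id, recording$label,
                 recording$sample_rate_hz,
                 matrix(out, nrow = nrow(recording$data)),
                 recording$channel_names, recording$event_log)
}

#' Cut a recording into fixed-length, non-overlapping segments
#'
#' Windows are anchored at the first sample; the trailing remainder shorter
#' than `window_len` is dropped. Windows containing any non-finite value are
#' excluded as corrupted. Every kept segment inherits the recording's label
#' and carries provenance `"ORIGINAL"`.
#'
#' @param recording a [gait_recording()].
#' @param window_len window length in samples (default 125 = 5 s at 25 Hz).
#' @return List of [gait_segment()] objects (possibly empty).
#' @export
segment_recording <- function(recording, window_len = 125) {
  if (window_len < 2) stop("window_len must be at least 2", call. = FALSE)
  n_seg <- floor(nrow(recording$data) / window_len)
  segs <- vector("list", n_seg)
  keep <- logical(n_seg)
  for (i in seq_len(n_seg)) {
    rows <- ((i - 1L) * window_len + 1L):(i * window_len)
    win <- recording$data[rows, , drop = FALSE]
    if (all(is.finite(win))) {
      segs[[i]] <- gait_segment(win, recording$label, recording$subject_id,
                                segment_index = i)
      keep[i] <- TRUE
    }
  }
  segs[keep]
}

#' Run the full preprocessing chain on one recording
#'
#' Applies, in fixed order, resampling, Savitzky-Golay smoothing, Butterworth
#' low-pass filtering, and z-normalization. The chain is a pure function of
#' `(recording, config)`.
#'
#' @param recording a [gait_recording()].
#' @param config a [preprocess_config()].
#' @return The conditioned [gait_recording()].
#' @export
preprocess_recording <- function(recording, config = preprocess_config()) {
  rec <- resample_recording(recording, config$target_rate_hz)
  rec <- savitzky_golay(rec, config)
  rec <- butterworth_lowpass(rec, config)
  znormalize(rec)
}

#' Preprocess and segment a whole cohort
#'
#' Convenience wrapper: [preprocess_recording()] followed by
#' [segment_recording()] for every recording, with the segment lists
#' concatenated. Segments never cross subject boundaries.
#'
#' @param recordings list of [gait_recording()] objects.
#' @param config a [preprocess_config()].
#' @param window_len segment length in samples.
#' @return List of [gait_segment()] objects.
#' @export
preprocess_cohort <- function(recordings, config = preprocess_config(),
                              window_len = 125) {
  unlist(lapply(recordings, function(r) {
    segment_recording(preprocess_recording(r, config), window_len)
  }), recursive = FALSE)
}
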