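# Filtering, resampling to the common 256 Hz rate, and 5-second windowing.

# Zero-phase filtering with even (symmetric) reflection padding at both
# ends; the padding length scales with the filter's time constant so that
# low cutoffs (0.5 Hz) do not leak edge transients into the signal body.
# Even reflection keeps the pad's mean level equal to the signal's: an odd
# (point-symmetric) pad would sit around 2*x(end), forming a DC pulse whose
# filtered step response bleeds across the junction — through a low-pass
# directly, and through a slow high-pass via its long settling tail.
zero_phase <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(pad))
  if (pad < 1L) return(signal::filtfilt(filt, x))
  pre <- x[(pad + 1):2]
  post <- x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(pad + 1):(pad + n)]
}

#' Band-limit a recording with zero-phase Butterworth filters
#'
#' Applies a 4th-order high-pass filter (always) and optionally a 4th-order
#' low-pass filter, each run forward-backward so band-power features see no
#' phase distortion. The scalp-EEG profile uses `highpass_hz = 0.5` and
#' `lowpass_hz = 60`; intracranial data typically use the high-pass alone
#' (`lowpass_hz = NULL`).
#'
#' @param recording a `recording`.
#' @param highpass_hz high-pass cutoff in Hz (default 0.5).
#' @param lowpass_hz low-pass cutoff in Hz, or `NULL` for none.
#' @return the filtered `recording` (same shape and sampling rate).
#' @export
apply_filters <- function(recording, highpass_hz = 0.5, lowpass_hz = NULL) {
  fs <- recording$fs
  nyq <- fs / 2
  if (highpass_hz >= nyq) stop_config("highpass cutoff must be below Nyquist")
  if (!is.null(lowpass_hz) && lowpass_hz >= nyq) {
    stop_config("lowpass cutoff must be below Nyquist")
  }
  hp <- signal::butter(4, highpass_hz / nyq, type = "high")
  pad_hp <- ceiling(3 * fs / highpass_hz)
  lp <- if (!is.null(lowpass_hz)) signal::butter(4, lowpass_hz / nyq, type = "low")
  out <- recording
  for (ch in seq_len(nrow(recording$signal))) {
    y <- zero_phase(hp, recording$signal[ch, ], pad_hp)
    if (!is.null(lp)) {
      y <- zero_phase(lp, y, max(64L, ceiling(3 * fs / lowpass_hz)))
    }
    out$signal[ch, ] <- y
  }
  out
}

#' Resample a recording to a lower common rate
#'
#' Polyphase anti-aliased resampling by a rational factor (the default
#' target is the pipeline's common 256 Hz rate). Non-integer ratios such as
#' 5000 -> 256 are approximated by a small rational fraction. Seizure
#' annotations are in seconds and are unchanged. Upsampling is refused.
#'
#' @param recording a `recording`.
#' @param target_fs target sampling rate in Hz (default 256).
#' @return the resampled `recording` with
#'   `round(duration * target_fs)` samples per channel.
#' @export
resample_to <- function(recording, target_fs = 256) {
  fs <- recording$fs
  if (target_fs > fs) stop_config("upsampling not supported")
  if (target_fs == fs) return(recording)
  frac <- rational_approx(target_fs / fs)
  n_out <- round(recording_duration(recording) * target_fs)
  sig <- matrix(0, nrow(recording$signal), n_out)
  for (ch in seq_len(nrow(recording$signal))) {
    y <- signal::resample(recording$signal[ch, ], frac[1], frac[2])
    if (length(y) >= n_out) y <- y[seq_len(n_out)]
    else y <- c(y, rep(y[length(y)], n_out - length(y)))
    sig[ch, ] <- y
  }
  out <- recording
  out$signal <- sig
  out$fs <- target_fs
  out
}

# Continued-fraction rational approximation of a ratio in (0, 1].
rational_approx <- function(r, max_den = 10000) {
  stopifnot(r > 0, r <= 1)
  # try exact small fraction first
  for (q in 1:640) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9 && round(p) >= 1) return(c(round(p), q))
  }
  best <- c(1, 1); err <- Inf
  for (q in 1:max_den) {
    p <- max(1, round(r * q))
    e <- abs(p / q - r)
    if (e < err) { err <- e; best <- c(p, q) }
    if (err < 1e-12) break
  }
  best
}

#' Cut a signal into non-overlapping fixed-length windows
#'
#' Partitions a continuous recording (or one segment of a segmented dataset)
#' into contiguous non-overlapping windows of `window_length` seconds; the
#' trailing remainder after the last full window is discarded. For a
#' `recording`, window start times (seconds) are kept; for a
#' `segmented_dataset`, windows carry `(segment_id, index)` keys plus the
#' segment's label and group, and no absolute times exist.
#'
#' @param x a `recording`, a `segmented_dataset`, or a channels-x-samples
#'   matrix (with `fs` supplied).
#' @param window_length window length in seconds (default 5).
#' @param fs sampling rate, required only for the matrix method.
#' @return a `window_set`: `windows` array (n_windows x channels x samples),
#'   `fs`, `window_length`, and either `start_times` or a `keys` data frame.
#' @export
make_windows <- function(x, window_length = 5, fs = NULL) {
  UseMethod("make_windows")
}

windows_from_matrix <- function(sig, fs, window_length) {
  spw <- round(fs * window_length)
  n_win <- floor(ncol(sig) / spw)
  if (n_win == 0) {
    warning("data shorter than one window; returning empty window set")
    return(array(0, c(0, nrow(sig), spw)))
  }
  w <- array(0, c(n_win, nrow(sig), spw))
  for (ch in seq_len(nrow(sig))) {
    w[, ch, ] <- matrix(sig[ch, seq_len(n_win * spw)], nrow = n_win,
                        byrow = TRUE)
  }
  w
}

#' @export
make_windows.recording <- function(x, window_length = 5, fs = NULL) {
  w <- windows_from_matrix(x$signal, x$fs, window_length)
  structure(list(
    windows = w, fs = x$fs, window_length = window_length,
    start_times = x$start_time + (seq_len(dim(w)[1]) - 1) * window_length,
    seizure_onsets = x$seizure_onsets
  ), class = "window_set")
}

#' @export
make_windows.matrix <- function(x, window_length = 5, fs = NULL) {
  if (is.null(fs)) stop_config("fs required for matrix input")
  w <- windows_from_matrix(x, fs, window_length)
  structure(list(
    windows = w, fs = fs, window_length = window_length,
    start_times = (seq_len(dim(w)[1]) - 1) * window_length
  ), class = "window_set")
}

#' @export
make_windows.segmented_dataset <- function(x, window_length = 5, fs = NULL) {
  per <- lapply(seq_along(x$segments), function(i) {
    s <- x$segments[[i]]
    w <- windows_from_matrix(s$data, x$fs, window_length)
    list(w = w, keys = data.frame(
      segment_id = i, index = seq_len(dim(w)[1]),
      label = s$label, group_id = s$group_id, stringsAsFactors = FALSE
    ))
  })
  w <- do.call(abind1, lapply(per, `[[`, "w"))
  structure(list(
    windows = w, fs = x$fs, window_length = window_length,
    keys = do.call(rbind, lapply(per, `[[`, "keys"))
  ), class = "window_set")
}

# bind 3-d arrays along the first dimension
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], 0)), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    n <- dim(p)[1]
    if (n > 0) out[at + seq_len(n), , ] <- p
    at <- at + n
  }
  out
}

#' @export
print.window_set <- function(x, ...) {
  d <- dim(x$windows)
  cat(sprintf("<window_set> %d window(s) x %d channel(s) x %d samples (%g s at %g Hz)\n",
              d[1], d[2], d[3], x$window_length, x$fs))
  invisible(x)
}
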