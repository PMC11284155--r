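# Firing Power regularization and refractory-governed alarm generation.

#' Firing Power series from binary classifier outputs
#'
#' The Firing Power at window n is the moving average of the last `tau`
#' binary outputs, where `tau` is the number of windows spanning one
#' preictal period (SOP + SPH). The warm-up is zero-padded: outputs before
#' the first window count as 0, which conservatively suppresses early
#' alarms rather than inflating the early average.
#'
#' @param outputs 0/1 vector of per-window classifier outputs.
#' @param tau moving-average length in windows (>= 1).
#' @return a `firing_power_series`: `values` in `[0, 1]` and `tau`.
#' @export
firing_power <- function(outputs, tau) {
  if (tau < 1) stop_config("tau must be >= 1")
  if (any(is.na(outputs)) || !all(outputs %in% c(0, 1))) {
    stop_config("outputs must be binary 0/1")
  }
  n <- length(outputs)
  cs <- cumsum(c(rep(0, tau), outputs))
  fp <- (cs[(tau + 1):(tau + n)] - cs[seq_len(n)]) / tau
  structure(list(values = fp, tau = tau), class = "firing_power_series")
}

#' Raise alarms from a Firing Power series
#'
#' An alarm fires at an upward threshold crossing (Firing Power at or above
#' `threshold` after being below it), outside the refractory span of the
#' previous alarm. With `retrigger = TRUE` (sustained-alert behavior), a
#' Firing Power still above threshold when the refractory period expires
#' retriggers immediately without a new crossing; with
#' `retrigger = FALSE`, it must first fall below the threshold and cross
#' again.
#'
#' @param fp a `firing_power_series` or numeric vector in `[0, 1]`.
#' @param threshold alarm threshold in (0, 1), default 0.7.
#' @param refractory refractory period in seconds (normally
#'   `(sop + sph) * 60`).
#' @param window_length window length in seconds (converts indices to
#'   times).
#' @param times optional window start times; defaults to
#'   `0, window_length, ...`.
#' @param retrigger sustained-alert retriggering flag (default `TRUE`).
#' @return an `alarm_series`: `times`, `indices`, `fp_values`,
#'   `refractory`.
#' @export
raise_alarms <- function(fp, threshold = 0.7, refractory,
                         window_length = 5, times = NULL,
                         retrigger = TRUE) {
  if (threshold <= 0 || threshold >= 1) stop_config("threshold must be in (0, 1)")
  v <- if (inherits(fp, "firing_power_series")) fp$values else fp
  n <- length(v)
  if (is.null(times)) times <- (seq_len(n) - 1) * window_length
  alarm_idx <- integer(0)
  last_alarm <- -Inf
  prev <- 0                                      # fp before the first window
  for (i in seq_len(n)) {
    in_refr <- times[i] < last_alarm + refractory
    if (!in_refr && v[i] >= threshold) {
      was_refr <- if (i > 1) times[i - 1] < last_alarm + refractory else FALSE
      crossing <- prev < threshold
      if (crossing || (retrigger && was_refr)) {
        alarm_idx <- c(alarm_idx, i)
        last_alarm <- times[i]
      }
    }
    prev <- v[i]
  }
  structure(list(
    times = times[alarm_idx], indices = alarm_idx,
    fp_values = v[alarm_idx], refractory = refractory
  ), class = "alarm_series")
}

#' @export
print.alarm_series <- function(x, ...) {
  cat(sprintf("<alarm_series> %d alarm(s), refractory %g s\n",
              length(x$times), x$refractory))
  invisible(x)
}
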