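# Statistical validation against chance by randomizing seizure onset times
# (alarm regime) or circularly shifting the label sequence (sample regime).

#' Draw surrogate seizure onset times
#'
#' Onsets are drawn uniformly over the admissible interictal portion of the
#' test period: at least one preictal span `(sop + sph) * 60` after the test
#' start (so a full preictal period fits), pairwise separated by at least
#' that span, and (by default) outside a +/- one-span exclusion zone around
#' each real onset so surrogate sensitivity is not trivially inflated by
#' the real alarms. Rejection sampling; deterministic given `seed`.
#'
#' @param test_start,test_end test period bounds in seconds.
#' @param n_seizures number of surrogate onsets to place.
#' @param spacing minimum pairwise separation in seconds (one preictal
#'   span).
#' @param real_onsets real onsets to avoid (used when
#'   `exclude_real = TRUE`).
#' @param exclude_real exclude zones around real onsets (default `TRUE`).
#' @param seed integer seed.
#' @return sorted numeric vector of `n_seizures` onset times.
#' @export
surrogate_onsets <- function(test_start, test_end, n_seizures, spacing,
                             real_onsets = numeric(0), exclude_real = TRUE,
                             seed = 1) {
  lo <- test_start + spacing
  if (lo >= test_end) stop("test period too short to place surrogate onsets")
  # admissible intervals after removing exclusion zones
  iv <- matrix(c(lo, test_end), ncol = 2)
  if (exclude_real && length(real_onsets)) {
    for (on in real_onsets) {
      iv <- interval_minus(iv, on - spacing, on + spacing)
    }
  }
  if (!nrow(iv)) stop("no admissible interictal time for surrogate onsets")
  len <- iv[, 2] - iv[, 1]
  with_seed(seed, {
    for (try in seq_len(10000)) {
      u <- stats::runif(n_seizures, 0, sum(len))
      cs <- cumsum(len)
      pick <- findInterval(u, c(0, cs), rightmost.closed = TRUE)
      cand <- sort(iv[pick, 1] + (u - c(0, cs)[pick]))
      if (n_seizures < 2 || all(diff(cand) >= spacing)) return(cand)
    }
    stop("could not place ", n_seizures,
         " surrogate onsets with the required separation")
  })
}

interval_minus <- function(iv, lo, hi) {
  out <- NULL
  for (r in seq_len(nrow(iv))) {
    a <- iv[r, 1]; b <- iv[r, 2]
    if (hi <= a || lo >= b) { out <- rbind(out, c(a, b)); next }
    if (lo > a) out <- rbind(out, c(a, lo))
    if (hi < b) out <- rbind(out, c(hi, b))
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

# Decision rule shared by both surrogate tests. The "ttest" method is a
# one-sided location test of the observed statistic against the surrogate
# distribution on the single-draw scale: under exchangeability the observed
# value is one more draw from the surrogate distribution, so the rejection
# region obs > mean + t_{1-alpha, n-1} * sd * sqrt(1 + 1/n) holds the
# type-I error near alpha. (A t test of the surrogate *mean* against the
# observed value rejects at obs > mean + t * sd / sqrt(n) and has type-I
# error near 40%, which is why it is not offered.) The "rank" method
# validates only when the observed statistic strictly exceeds every
# surrogate (p = 1/(n+1)).
surrogate_decision <- function(observed, surrogates, alpha, method) {
  n <- length(surrogates)
  m <- mean(surrogates)
  s <- stats::sd(surrogates)
  degenerate <- FALSE
  if (method == "rank") {
    p <- (1 + sum(surrogates >= observed)) / (n + 1)
  } else {
    if (s < 1e-12) {
      degenerate <- TRUE
      p <- if (observed > m) 0 else 1
    } else {
      t_stat <- (observed - m) / (s * sqrt(1 + 1 / n))
      p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
    }
  }
  validated <- is.finite(p) && p < alpha && observed > m
  if (degenerate && observed <= m) validated <- FALSE
  structure(list(
    observed_statistic = observed, surrogate_statistics = surrogates,
    p_value = p, validated = validated, alpha = alpha, method = method,
    degenerate = degenerate
  ), class = "surrogate_result")
}

#' Surrogate test of alarm sensitivity
#'
#' Holding the real alarm times fixed, seizure onset times are randomized
#' `n_surrogates` times within the interictal portion of the test period
#' and the alarm sensitivity is recomputed against each surrogate onset
#' set. The patient is validated when the observed sensitivity is
#' significantly above the surrogate distribution at level `alpha`.
#'
#' @param alarms an `alarm_series` or vector of alarm times.
#' @param onsets real test onsets in seconds.
#' @param test_start,test_end,test_duration test period geometry in
#'   seconds.
#' @param sop,sph SOP and SPH in minutes.
#' @param config a [pipeline_config()] (supplies `n_surrogates`, `alpha`,
#'   `surrogate_method`, `blackout`, `seed`).
#' @return a `surrogate_result`.
#' @export
surrogate_test_alarm <- function(alarms, onsets, test_start, test_end,
                                 test_duration, sop, sph, config) {
  spacing <- (sop + sph) * 60
  obs <- alarm_metrics(alarms, onsets, sop, sph, test_duration,
                       blackout = config$blackout)$ss_alarm
  # if the exclusion zones around the real onsets leave no room (short test
  # periods with a long preictal span), fall back to unconstrained placement
  exclude <- tryCatch({
    surrogate_onsets(test_start, test_end, length(onsets), spacing,
                     real_onsets = onsets, seed = 0L)
    TRUE
  }, error = function(e) {
    warning("surrogate exclusion zones infeasible; placing surrogate ",
            "onsets without them")
    FALSE
  })
  surr <- vapply(seq_len(config$n_surrogates), function(i) {
    so <- surrogate_onsets(test_start, test_end, length(onsets), spacing,
                           real_onsets = onsets, exclude_real = exclude,
                           seed = derive_seed(config$seed, 300 + i))
    alarm_metrics(alarms, so, sop, sph, test_duration,
                  blackout = config$blackout)$ss_alarm
  }, 0)
  surrogate_decision(obs, surr, config$alpha, config$surrogate_method)
}

#' Surrogate test of sample sensitivity
#'
#' The truth-label sequence is circularly shifted by `n_surrogates`
#' distinct uniform offsets (offset 0 excluded), preserving its block and
#' autocorrelation structure, and the sample sensitivity of the fixed
#' classifier outputs is recomputed against each shifted labeling.
#'
#' @param truth 0/1 label sequence in timeline order.
#' @param binary 0/1 classifier outputs in the same order.
#' @param config a [pipeline_config()].
#' @return a `surrogate_result`.
#' @export
surrogate_test_sample <- function(truth, binary, config) {
  keep <- !is.na(truth)
  truth <- truth[keep]; binary <- binary[keep]
  n <- length(truth)
  if (n < 4) stop("label sequence too short for circular surrogates")
  obs <- sum(truth == 1 & binary == 1) / sum(truth == 1)
  shifts <- with_seed(derive_seed(config$seed, 400),
                      sample(seq_len(n - 1), config$n_surrogates,
                             replace = config$n_surrogates > n - 1))
  surr <- vapply(shifts, function(s) {
    ts <- c(truth[(s + 1):n], truth[seq_len(s)])
    if (sum(ts == 1) == 0) return(0)
    sum(ts == 1 & binary == 1) / sum(ts == 1)
  }, 0)
  surrogate_decision(obs, surr, config$alpha, config$surrogate_method)
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf(
    "<surrogate_result> observed %.3f vs %d surrogates (mean %.3f), p = %.4f -> %svalidated\n",
    x$observed_statistic, length(x$surrogate_statistics),
    mean(x$surrogate_statistics), x$p_value,
    if (x$validated) "" else "not "))
  invisible(x)
}
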