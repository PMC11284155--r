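# Alarm-based (sensitivity, FPR/h) and sample-based (SS, SP, AUC)
# evaluation.

#' Alarm-based performance metrics
#'
#' An alarm at time t is a true alarm when some seizure onset falls inside
#' its prediction window `[t + sph*60, t + (sph + sop)*60]` -- the seizure
#' must not occur during the SPH but must occur during the SOP. Each
#' seizure counts as predicted at most once; a single alarm whose window
#' covers several onsets predicts each of them (rare under the refractory
#' period; disable with `multi_onset = FALSE`). FPR/h divides false alarms
#' by interictal hours: the test duration minus each seizure's preictal
#' span and ictal blackout (set `denominator = "total"` for total
#' monitored time).
#'
#' @param alarms an `alarm_series` or numeric vector of alarm times
#'   (seconds).
#' @param onsets test seizure onsets in seconds.
#' @param sop,sph SOP and SPH in minutes.
#' @param test_duration monitored test time in seconds.
#' @param blackout ictal blackout per seizure in seconds.
#' @param denominator `"interictal"` or `"total"`.
#' @param multi_onset may one alarm predict several onsets?
#' @return an `alarm_metrics` list: `ss_alarm`, `fpr_per_hour`,
#'   `n_true_alarms`, `n_false_alarms`, `interictal_hours`.
#' @export
alarm_metrics <- function(alarms, onsets, sop, sph, test_duration,
                          blackout = 120,
                          denominator = c("interictal", "total"),
                          multi_onset = TRUE) {
  denominator <- match.arg(denominator)
  at <- if (inherits(alarms, "alarm_series")) alarms$times else alarms
  span <- (sop + sph) * 60
  predicted <- rep(FALSE, length(onsets))
  true_alarm <- rep(FALSE, length(at))
  for (i in seq_along(at)) {
    lo <- at[i] + sph * 60
    hi <- at[i] + span
    hit <- which(onsets >= lo & onsets <= hi)
    if (length(hit)) {
      true_alarm[i] <- TRUE
      if (!multi_onset) hit <- hit[1]
      predicted[hit] <- TRUE
    }
  }
  n_true <- sum(true_alarm)
  n_false <- sum(!true_alarm)
  hours <- if (denominator == "total") {
    test_duration / 3600
  } else {
    (test_duration - length(onsets) * (span + blackout)) / 3600
  }
  if (hours <= 0) stop("no interictal time in the test period")
  list(
    ss_alarm = if (length(onsets)) mean(predicted) else NA_real_,
    fpr_per_hour = n_false / hours,
    n_true_alarms = n_true, n_false_alarms = n_false,
    n_predicted = sum(predicted), n_seizures = length(onsets),
    interictal_hours = hours
  )
}

#' Mann-Whitney rank AUC
#'
#' @param scores continuous scores.
#' @param truth 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth) {
  r <- rank(scores)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sample-based performance metrics
#'
#' Window-by-window sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`
#' from the binary outputs, and the rank-statistic AUC from the continuous
#' scores.
#'
#' @param truth 0/1 labels (`NA` rows dropped along with their outputs).
#' @param binary 0/1 classifier outputs.
#' @param scores continuous classifier scores (default = `binary`).
#' @return a `sample_metrics` list: `ss_sample`, `sp_sample`, `auc`.
#' @export
sample_metrics <- function(truth, binary, scores = binary) {
  keep <- !is.na(truth)
  truth <- truth[keep]; binary <- binary[keep]; scores <- scores[keep]
  if (length(unique(truth)) < 2) {
    stop("both classes required for sample metrics")
  }
  tp <- sum(truth == 1 & binary == 1); fn <- sum(truth == 1 & binary == 0)
  tn <- sum(truth == 0 & binary == 0); fp <- sum(truth == 0 & binary == 1)
  list(
    ss_sample = tp / (tp + fn),
    sp_sample = tn / (tn + fp),
    auc = auc_rank(scores, truth)
  )
}
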