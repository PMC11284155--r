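# End-to-end experiment runners for the two data regimes, and dataset-level
# summaries.

#' Run the full continuous-regime experiment on one patient
#'
#' Executes the complete pipeline on a continuous annotated recording:
#' filtering, resampling to the common rate, 5-s windowing, feature
#' extraction, chronological train/test split, SOP/feature-count grid
#' search with seizure-wise cross-validation, final class-weighted
#' logistic training, per-window prediction on the test timeline, Firing
#' Power regularization and refractory alarm generation, alarm-based and
#' sample-based metrics, and both surrogate tests.
#'
#' @param recording a `recording` with at least four annotated seizures.
#' @param config a [pipeline_config()].
#' @param patient_id identifier recorded in the report.
#' @return an `experiment_report` list: `regime`, `sop_star`, `k_star`,
#'   `alarm_metrics`, `sample_metrics`, `surrogate_alarm`,
#'   `surrogate_sample`, `model`, `config`.
#' @export
run_continuous_experiment <- function(recording, config = pipeline_config(),
                                      patient_id = "patient") {
  rec <- apply_filters(recording, config$highpass_hz, config$lowpass_hz)
  if (rec$fs > config$target_fs) rec <- resample_to(rec, config$target_fs)
  ws <- make_windows(rec, config$window_length)
  fm <- extract_features(ws)
  split <- chronological_split(fm, rec$seizure_onsets,
                               config$n_train_seizures)

  cv <- cv_grid_search(split, config)
  sop_star <- cv$sop_star

  train_labels <- label_windows(split$train_times, split$train_onsets,
                                sop_star, config$sph, config$blackout)
  model <- train_classifier(split$train_values, train_labels,
                            sop_star, cv$k_star,
                            feature_names = split$feature_names)

  pred <- predict(model, split$test_values)
  tau <- round((sop_star + config$sph) * 60 / config$window_length)
  fp <- firing_power(pred$binary, tau)
  refractory <- (sop_star + config$sph) * 60
  alarms <- raise_alarms(fp, config$fp_threshold, refractory,
                         window_length = config$window_length,
                         times = split$test_times,
                         retrigger = config$retrigger)

  test_end <- max(split$test_times) + config$window_length
  test_duration <- test_end - split$test_start
  am <- alarm_metrics(alarms, split$test_onsets, sop_star, config$sph,
                      test_duration, blackout = config$blackout,
                      denominator = config$fpr_denominator)

  test_labels <- label_windows(split$test_times, split$test_onsets,
                               sop_star, config$sph, config$blackout)
  sm <- sample_metrics(test_labels, pred$binary, pred$probability)

  sa <- surrogate_test_alarm(alarms, split$test_onsets, split$test_start,
                             test_end, test_duration, sop_star,
                             config$sph, config)
  ss <- surrogate_test_sample(test_labels, pred$binary, config)

  structure(list(
    patient_id = patient_id, regime = "continuous",
    sop_star = sop_star, k_star = model$k_star,
    cv_table = cv$table,
    alarm_metrics = am, sample_metrics = sm,
    surrogate_alarm = sa, surrogate_sample = ss,
    model = model, alarms = alarms, config = config
  ), class = "experiment_report")
}

#' Run the segmented-regime experiment on one patient
#'
#' The pipeline for temporally anonymized labeled clips: the preictal
#' period is fixed by the file labels (no SOP grid), splits and class
#' balancing operate at the file level, evaluation is sample-by-sample
#' only, and validation uses the circular label-shift surrogate. The
#' report contains no alarm metrics: without absolute timestamps no alarm
#' can be raised, so sensitivity/FPR-per-hour are structurally undefined
#' in this regime.
#'
#' @param dataset a `segmented_dataset` with at least two preictal groups.
#' @param config a [pipeline_config()].
#' @param patient_id identifier recorded in the report.
#' @return an `experiment_report` with `alarm_metrics = NULL` and
#'   `surrogate_alarm = NULL`.
#' @export
run_segmented_experiment <- function(dataset, config = pipeline_config(),
                                     patient_id = "patient") {
  sp <- segmented_split(dataset, seed = derive_seed(config$seed, 10))
  ws <- make_windows(dataset, config$window_length)
  fm <- extract_features(ws)
  seg_of <- fm$keys$segment_id
  lab_all <- as.integer(fm$keys$label == "preictal")

  tr <- seg_of %in% sp$train_segments
  xtr <- fm$values[tr, , drop = FALSE]
  ytr <- lab_all[tr]
  k_star <- cv_select_k_segmented(xtr, ytr, fm$keys$group_id[tr], config)

  model <- train_classifier(xtr, ytr, sop_star = NA, k_star = k_star,
                            feature_names = fm$feature_names)
  te <- !tr
  pred <- predict(model, fm$values[te, , drop = FALSE])
  # timeline order for the circular surrogate: by segment, then window
  ord <- order(seg_of[te], fm$keys$index[te])
  sm <- sample_metrics(lab_all[te], pred$binary, pred$probability)
  ss <- surrogate_test_sample(lab_all[te][ord], pred$binary[ord], config)

  structure(list(
    patient_id = patient_id, regime = "segmented",
    sop_star = NA_real_, k_star = model$k_star,
    alarm_metrics = NULL, sample_metrics = sm,
    surrogate_alarm = NULL, surrogate_sample = ss,
    model = model, config = config
  ), class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s (%s regime)\n", x$patient_id, x$regime))
  if (!is.null(x$alarm_metrics)) {
    cat(sprintf("  SOP* %g min, k* %d | SS_alarm %.2f, FPR/h %.2f\n",
                x$sop_star, x$k_star, x$alarm_metrics$ss_alarm,
                x$alarm_metrics$fpr_per_hour))
  } else {
    cat(sprintf("  k* %d (preictal period fixed by file labels)\n", x$k_star))
  }
  cat(sprintf("  SS_sample %.2f, SP_sample %.2f, AUC %.2f\n",
              x$sample_metrics$ss_sample, x$sample_metrics$sp_sample,
              x$sample_metrics$auc))
  if (!is.null(x$surrogate_alarm)) {
    cat(sprintf("  surrogate (alarm): p = %.3f, %svalidated\n",
                x$surrogate_alarm$p_value,
                if (x$surrogate_alarm$validated) "" else "not "))
  }
  cat(sprintf("  surrogate (sample): p = %.3f, %svalidated\n",
              x$surrogate_sample$p_value,
              if (x$surrogate_sample$validated) "" else "not "))
  invisible(x)
}

report_row <- function(r) {
  am <- r$alarm_metrics
  data.frame(
    patient_id = r$patient_id, regime = r$regime,
    sop_star = r$sop_star, k_star = r$k_star,
    ss_alarm = if (is.null(am)) NA_real_ else am$ss_alarm,
    fpr_per_hour = if (is.null(am)) NA_real_ else am$fpr_per_hour,
    ss_sample = r$sample_metrics$ss_sample,
    sp_sample = r$sample_metrics$sp_sample,
    auc = r$sample_metrics$auc,
    validated_alarm = if (is.null(r$surrogate_alarm)) NA
                      else r$surrogate_alarm$validated,
    validated_sample = r$surrogate_sample$validated,
    stringsAsFactors = FALSE
  )
}

#' Summarize experiment reports into a dataset-level table
#'
#' One row per patient plus dataset-level means and validated-patient
#' counts/percentages; metrics absent in a regime (alarm metrics for
#' segmented patients) are excluded from means.
#'
#' @param reports list of `experiment_report` objects.
#' @return list with `patients` (per-patient data.frame) and `summary`
#'   (means, validated counts and percentages).
#' @export
summarize_experiments <- function(reports) {
  if (!length(reports)) stop_config("no reports to summarize")
  rows <- do.call(rbind, lapply(reports, report_row))
  num <- c("ss_alarm", "fpr_per_hour", "ss_sample", "sp_sample", "auc")
  means <- vapply(num, function(cn) mean(rows[[cn]], na.rm = TRUE), 0)
  n_alarm <- sum(!is.na(rows$validated_alarm))
  summary <- list(
    means = means,
    n_patients = nrow(rows),
    validated_alarm = sum(rows$validated_alarm, na.rm = TRUE),
    pct_validated_alarm = if (n_alarm) {
      100 * sum(rows$validated_alarm, na.rm = TRUE) / n_alarm
    } else NA_real_,
    validated_sample = sum(rows$validated_sample),
    pct_validated_sample = 100 * mean(rows$validated_sample)
  )
  list(patients = rows, summary = summary)
}
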