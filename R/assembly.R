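# SOP/SPH labeling, chronological and file-level splitting, class
# balancing, and train-fitted z-score normalization.

#' Pipeline configuration
#'
#' Collects every tunable of the prediction pipeline with the defaults used
#' throughout: a 10-min SPH (time for intervention), an SOP grid of 10-55
#' min in 5-min steps bounded by the 1-h preictal cap, a Firing Power alarm
#' threshold of 0.7, three training seizures (the minimum supporting
#' two-train/one-validate seizure-wise cross-validation), 30 surrogates at
#' a 0.05 significance level, 5-s windows at the common 256 Hz rate.
#'
#' @param sph seizure prediction horizon in minutes.
#' @param sop_grid candidate seizure occurrence periods in minutes.
#' @param preictal_cap maximum preictal (SOP) duration in minutes.
#' @param fp_threshold Firing Power alarm threshold in (0, 1).
#' @param n_train_seizures seizures assigned to training in the continuous
#'   regime.
#' @param n_surrogates number of surrogate randomizations.
#' @param alpha significance level for surrogate validation.
#' @param window_length analysis window length in seconds.
#' @param target_fs common sampling rate in Hz.
#' @param highpass_hz,lowpass_hz filter cutoffs; set `lowpass_hz = NULL`
#'   for the intracranial profile.
#' @param k_grid candidate numbers of selected features for the grid search.
#' @param blackout ictal/postictal blackout after each onset, seconds.
#' @param surrogate_method `"rank"` (default: validated only when the
#'   observed statistic strictly exceeds every surrogate, p = 1/31) or
#'   `"ttest"` (one-sided location test of the observed statistic against
#'   the surrogate distribution on the single-draw scale). The rank rule
#'   holds its nominal level for the discrete alarm-sensitivity statistic;
#'   the t variant is anticonservative there (see the methods vignette).
#' @param retrigger may an above-threshold Firing Power retrigger an alarm
#'   immediately after the refractory period expires?
#' @param fpr_denominator `"interictal"` (default) or `"total"` monitored
#'   time in the FPR/h denominator.
#' @param seed master seed; all stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sph = 10,
                            sop_grid = seq(10, 55, by = 5),
                            preictal_cap = 60,
                            fp_threshold = 0.7,
                            n_train_seizures = 3,
                            n_surrogates = 30,
                            alpha = 0.05,
                            window_length = 5,
                            target_fs = 256,
                            highpass_hz = 0.5,
                            lowpass_hz = 60,
                            k_grid = c(5, 10, 20, 40),
                            blackout = 120,
                            surrogate_method = c("rank", "ttest"),
                            retrigger = TRUE,
                            fpr_denominator = c("interictal", "total"),
                            seed = 1) {
  if (sph <= 0) stop_config("sph must be positive")
  if (any(sop_grid < 10) || any(sop_grid > preictal_cap)) {
    stop_config("sop values must lie in [10, preictal_cap] minutes")
  }
  if (fp_threshold <= 0 || fp_threshold >= 1) {
    stop_config("fp_threshold must be in (0, 1)")
  }
  structure(list(
    sph = sph, sop_grid = sop_grid, preictal_cap = preictal_cap,
    fp_threshold = fp_threshold, n_train_seizures = n_train_seizures,
    n_surrogates = n_surrogates, alpha = alpha,
    window_length = window_length, target_fs = target_fs,
    highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
    k_grid = k_grid, blackout = blackout,
    surrogate_method = match.arg(surrogate_method),
    retrigger = retrigger,
    fpr_denominator = match.arg(fpr_denominator),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Label windows with the SOP/SPH scheme
#'
#' A window is preictal (1) when its start time falls in
#' `[onset - (sop + sph) * 60, onset)` for some onset; windows inside an
#' ictal/postictal blackout `[onset, onset + blackout]` are excluded
#' (`NA`); everything else is interictal (0). The preictal class spans the
#' SPH and the SOP, and is truncated at the recording start.
#'
#' @param window_times window start times in seconds.
#' @param onsets seizure onset times in seconds, sorted.
#' @param sop seizure occurrence period in minutes.
#' @param sph seizure prediction horizon in minutes.
#' @param blackout ictal blackout in seconds (default 120).
#' @return integer vector: 1 preictal, 0 interictal, `NA` excluded.
#' @export
label_windows <- function(window_times, onsets, sop, sph, blackout = 120) {
  lab <- rep(0L, length(window_times))
  span <- (sop + sph) * 60
  for (on in onsets) {
    lab[window_times >= on - span & window_times < on] <- 1L
    lab[window_times >= on & window_times <= on + blackout] <- NA_integer_
  }
  lab
}

#' Chronological train/test split for the continuous regime
#'
#' The first `n_train_seizures` seizures, and every window up to a cut
#' point one hour after the last training onset, form the training set; all
#' later windows and seizures form the test set, whose timeline is kept for
#' alarm evaluation. Patients with fewer than four seizures are excluded
#' (too few to train on three and test on at least one).
#'
#' @param fm a `feature_matrix` from a continuous recording.
#' @param onsets all seizure onsets in seconds.
#' @param n_train_seizures number of initial seizures for training.
#' @return a `labeled_split`: train/test values, times, and onset vectors.
#' @export
chronological_split <- function(fm, onsets, n_train_seizures = 3) {
  if (length(onsets) < 4) {
    stop_config("patient excluded: fewer than four seizures")
  }
  if (n_train_seizures >= length(onsets)) {
    stop_config("need at least one seizure left for testing")
  }
  cut <- onsets[n_train_seizures] + 3600
  times <- fm$keys$time
  tr <- times < cut
  structure(list(
    train_values = fm$values[tr, , drop = FALSE],
    train_times = times[tr],
    train_onsets = onsets[seq_len(n_train_seizures)],
    test_values = fm$values[!tr, , drop = FALSE],
    test_times = times[!tr],
    test_onsets = onsets[-seq_len(n_train_seizures)],
    test_start = cut,
    feature_names = fm$feature_names
  ), class = "labeled_split")
}

#' File-level train/test split for the segmented regime
#'
#' Whole preictal seizure groups are assigned to training or testing
#' (never split), with the training share as close as possible to 70%.
#' Training interictal files are subsampled to match the training preictal
#' file count (balanced training); all remaining files go to testing.
#'
#' @param dataset a `segmented_dataset`.
#' @param train_fraction preictal-group share assigned to training.
#' @param seed seed for the deterministic group assignment.
#' @return list with `train_segments` and `test_segments` (segment indices).
#' @export
segmented_split <- function(dataset, train_fraction = 0.7, seed = 1) {
  labs <- vapply(dataset$segments, `[[`, "", "label")
  gids <- vapply(dataset$segments, `[[`, 0, "group_id")
  pre_groups <- sort(unique(gids[labs == "preictal"]))
  if (length(pre_groups) < 2) {
    stop_config("cannot split: fewer than two preictal seizure groups")
  }
  n_train_g <- round(train_fraction * length(pre_groups))
  n_train_g <- max(1L, min(length(pre_groups) - 1L, n_train_g))
  assign <- with_seed(seed, sample(pre_groups))
  train_groups <- sort(assign[seq_len(n_train_g)])

  pre_idx <- which(labs == "preictal")
  int_idx <- which(labs == "interictal")
  train_pre <- pre_idx[gids[pre_idx] %in% train_groups]
  n_bal <- min(length(train_pre), length(int_idx))
  train_int <- with_seed(derive_seed(seed, 1),
                         sort(sample(int_idx, n_bal)))
  train <- sort(c(train_pre, train_int))
  list(train_segments = train,
       test_segments = sort(setdiff(seq_along(dataset$segments), train)),
       train_groups = train_groups)
}

#' Inverse-frequency class weights
#'
#' `weight_c = N_total / (2 * N_c)`, so the weighted class masses are equal
#' and balanced labels give unit weights.
#'
#' @param labels 0/1 vector with both classes present (`NA` ignored).
#' @return list with `weight_interictal` and `weight_preictal`.
#' @export
compute_class_weights <- function(labels) {
  labels <- labels[!is.na(labels)]
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  if (n0 == 0 || n1 == 0) stop_config("both classes required for class weights")
  n <- n0 + n1
  list(weight_interictal = n / (2 * n0), weight_preictal = n / (2 * n1))
}

#' Fit / apply z-score normalization
#'
#' `zscore_fit()` estimates per-feature mean and standard deviation on
#' training data only; `zscore_apply()` standardizes any matrix with those
#' parameters. Zero-variance training features are recorded and transformed
#' to zero so they carry no information downstream.
#'
#' @param x numeric matrix (windows x features).
#' @return `zscore_fit`: a `normalization_params` list (`center`, `scale`,
#'   `zero_variance` indices); `zscore_apply`: the standardized matrix.
#' @export
zscore_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  zero <- unname(which(!is.finite(scale) | scale < 1e-12))
  scale[zero] <- 1
  structure(list(center = center, scale = scale, zero_variance = zero),
            class = "normalization_params")
}

#' @rdname zscore_fit
#' @param params a `normalization_params` from [zscore_fit()].
#' @export
zscore_apply <- function(params, x) {
  z <- sweep(sweep(x, 2, params$center), 2, params$scale, `/`)
  if (length(params$zero_variance)) z[, params$zero_variance] <- 0
  z
}
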