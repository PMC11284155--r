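# Feature ranking, SOP/feature-count grid search with seizure-wise
# leave-one-out cross-validation, and the final class-weighted logistic
# classifier.

#' Rank features by univariate class separability
#'
#' Features are ordered by decreasing absolute two-sample (Welch) t
#' statistic between preictal and interictal windows; zero-variance
#' features sort last, and ties break deterministically by column index.
#'
#' @param x normalized training matrix (windows x features).
#' @param labels 0/1 labels (`NA` rows ignored).
#' @return integer vector of column indices, most separable first.
#' @export
rank_features <- function(x, labels) {
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) stop_config("both classes required for ranking")
  i1 <- labels == 1
  n1 <- sum(i1); n0 <- sum(!i1)
  m1 <- colMeans(x[i1, , drop = FALSE])
  m0 <- colMeans(x[!i1, , drop = FALSE])
  v1 <- apply(x[i1, , drop = FALSE], 2, stats::var)
  v0 <- apply(x[!i1, , drop = FALSE], 2, stats::var)
  se <- sqrt(v1 / n1 + v0 / n0)
  stat <- abs(m1 - m0) / se
  stat[!is.finite(stat)] <- -Inf                 # zero-variance features last
  order(-stat, seq_along(stat))
}

# Fit a weighted logistic model on selected columns and return a predictor.
# glm's "non-integer #successes" warning is an artifact of non-integer
# class weights and is suppressed.
fit_logistic <- function(x, labels, weights) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- labels
  w <- ifelse(labels == 1, weights$weight_preictal, weights$weight_interictal)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(), weights = w,
               control = stats::glm.control(maxit = 100)),
    warning = function(cond) {
      if (grepl("non-integer|fitted probabilities|did not converge",
                conditionMessage(cond))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) {
    stop("logistic fit did not converge (deviance ", signif(fit$deviance, 4),
         " after ", fit$iter, " iterations)")
  }
  fit
}

logistic_probs <- function(coefs, x) {
  coefs[is.na(coefs)] <- 0          # aliased (collinear) columns drop out
  eta <- drop(cbind(1, x) %*% coefs)
  stats::plogis(eta)
}

# Sample-based SS * SP objective on one validation fold.
fold_objective <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  ss <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ss * sp
}

#' Grid search over SOP and feature count with seizure-wise LOOCV
#'
#' For each candidate SOP, the training windows are relabeled with that
#' SOP; for each training seizure in turn, the model is fitted on the other
#' seizures' windows and evaluated on the held-out seizure's windows with
#' the sample sensitivity-times-specificity objective, for each candidate
#' feature count. The `(sop, k)` pair maximizing the mean fold objective is
#' selected; ties break to the smallest SOP, then the smallest k (the less
#' complex model). Folds without preictal or interictal validation windows
#' are skipped with a warning.
#'
#' @param split a `labeled_split` from [chronological_split()].
#' @param config a [pipeline_config()].
#' @return list with `sop_star`, `k_star`, and `table` (one row per
#'   `(sop, k)` with the mean objective and fold count).
#' @export
cv_grid_search <- function(split, config) {
  onsets <- split$train_onsets
  if (length(onsets) < 3) {
    stop_config("continuous-regime grid search needs at least 3 training seizures")
  }
  times <- split$train_times
  # seizure blocks: window belongs to the first seizure whose blackout end
  # it precedes; the tail goes to the last block
  bounds <- onsets + config$blackout
  fold_of <- findInterval(times, bounds, left.open = TRUE) + 1L
  fold_of[fold_of > length(onsets)] <- length(onsets)

  grid <- expand.grid(sop = config$sop_grid, k = config$k_grid)
  grid$objective <- NA_real_
  grid$n_folds <- 0L

  for (sop in config$sop_grid) {
    labels <- label_windows(times, onsets, sop, config$sph, config$blackout)
    per_fold <- vector("list", length(onsets))
    for (f in seq_along(onsets)) {
      vi <- fold_of == f & !is.na(labels)
      ti <- fold_of != f & !is.na(labels)
      if (sum(labels[vi] == 1) == 0 || sum(labels[vi] == 0) == 0 ||
          length(unique(labels[ti])) < 2) {
        warning("fold ", f, " skipped at sop ", sop,
                " (single-class fold)")
        next
      }
      xtr <- split$train_values[ti, , drop = FALSE]
      ytr <- labels[ti]
      xva <- split$train_values[vi, , drop = FALSE]
      yva <- labels[vi]
      norm <- zscore_fit(xtr)
      ztr <- zscore_apply(norm, xtr)
      zva <- zscore_apply(norm, xva)
      ranked <- rank_features(ztr, ytr)
      wts <- compute_class_weights(ytr)
      obj_k <- vapply(config$k_grid, function(k) {
        sel <- ranked[seq_len(min(k, ncol(ztr)))]
        fit <- fit_logistic(ztr[, sel, drop = FALSE], ytr, wts)
        pr <- logistic_probs(stats::coef(fit), zva[, sel, drop = FALSE])
        fold_objective(yva, as.integer(pr >= 0.5))
      }, 0)
      per_fold[[f]] <- obj_k
    }
    kept <- per_fold[!vapply(per_fold, is.null, TRUE)]
    if (!length(kept)) next
    mobj <- colMeans(do.call(rbind, kept))
    for (i in seq_along(config$k_grid)) {
      row <- grid$sop == sop & grid$k == config$k_grid[i]
      grid$objective[row] <- mobj[i]
      grid$n_folds[row] <- length(kept)
    }
  }
  if (all(is.na(grid$objective))) stop("all cross-validation folds skipped")
  # argmax; ties -> smallest sop, then smallest k
  ord <- order(-grid$objective, grid$sop, grid$k, na.last = TRUE)
  best <- grid[ord[1], ]
  list(sop_star = best$sop, k_star = best$k, table = grid)
}

# Feature-count selection for the segmented regime: the preictal period is
# fixed by the file labels, so only k is cross-validated, over seeded
# 70/30 file resplits of the training files.
cv_select_k_segmented <- function(x, labels, groups, config, n_folds = 3) {
  obj <- matrix(NA_real_, n_folds, length(config$k_grid))
  pre_groups <- sort(unique(groups[labels == 1]))
  for (f in seq_len(n_folds)) {
    gsub <- with_seed(derive_seed(config$seed, 100 + f), sample(pre_groups))
    n_tr <- max(1L, min(length(pre_groups) - 1L,
                        round(0.7 * length(pre_groups))))
    tr_groups <- gsub[seq_len(n_tr)]
    pre_tr <- labels == 1 & groups %in% tr_groups
    int_idx <- which(labels == 0)
    n_int_tr <- round(0.7 * length(int_idx))
    int_tr <- with_seed(derive_seed(config$seed, 200 + f),
                        sample(int_idx, n_int_tr))
    ti <- pre_tr | seq_along(labels) %in% int_tr
    vi <- !ti
    if (length(unique(labels[vi])) < 2 || length(unique(labels[ti])) < 2) next
    norm <- zscore_fit(x[ti, , drop = FALSE])
    ztr <- zscore_apply(norm, x[ti, , drop = FALSE])
    zva <- zscore_apply(norm, x[vi, , drop = FALSE])
    ranked <- rank_features(ztr, labels[ti])
    wts <- compute_class_weights(labels[ti])
    for (i in seq_along(config$k_grid)) {
      sel <- ranked[seq_len(min(config$k_grid[i], ncol(ztr)))]
      fit <- fit_logistic(ztr[, sel, drop = FALSE], labels[ti], wts)
      pr <- logistic_probs(stats::coef(fit), zva[, sel, drop = FALSE])
      obj[f, i] <- fold_objective(labels[vi], as.integer(pr >= 0.5))
    }
  }
  mobj <- colMeans(obj, na.rm = TRUE)
  if (all(!is.finite(mobj))) stop("all segmented cross-validation folds skipped")
  config$k_grid[order(-mobj, config$k_grid)[1]]
}

#' Train the final classifier
#'
#' Fits the class-weighted linear logistic model on the top `k_star` ranked
#' features of the normalized training data and packages everything needed
#' for prediction.
#'
#' @param x raw (unnormalized) training matrix.
#' @param labels 0/1 training labels (`NA` rows dropped).
#' @param sop_star selected SOP in minutes (recorded in the model).
#' @param k_star number of top-ranked features to use.
#' @param feature_names column names of `x`.
#' @return a `seizure_model` with coefficients, selected features,
#'   normalization parameters, and class weights.
#' @export
train_classifier <- function(x, labels, sop_star, k_star,
                             feature_names = colnames(x)) {
  keep <- !is.na(labels)
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  norm <- zscore_fit(x)
  z <- zscore_apply(norm, x)
  ranked <- rank_features(z, labels)
  sel <- ranked[seq_len(min(k_star, ncol(z)))]
  wts <- compute_class_weights(labels)
  fit <- fit_logistic(z[, sel, drop = FALSE], labels, wts)
  structure(list(
    coefficients = stats::coef(fit),
    selected = sel,
    selected_names = feature_names[sel],
    sop_star = sop_star, k_star = length(sel),
    normalization = norm, class_weights = wts
  ), class = "seizure_model")
}

#' Predict per-window seizure probability
#'
#' Applies the model's training normalization, evaluates the logistic
#' model on its selected features, and thresholds at 0.5.
#'
#' @param object a `seizure_model`.
#' @param newdata raw feature matrix with the training column layout.
#' @param ... unused.
#' @return data.frame with `probability` and `binary` (0/1 at 0.5).
#' @export
predict.seizure_model <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$normalization$center)) {
    stop_config("feature dimension mismatch: got ", ncol(newdata),
                ", model expects ", length(object$normalization$center))
  }
  z <- zscore_apply(object$normalization, newdata)
  pr <- logistic_probs(object$coefficients,
                       z[, object$selected, drop = FALSE])
  data.frame(probability = pr, binary = as.integer(pr >= 0.5))
}

#' @export
print.seizure_model <- function(x, ...) {
  cat(sprintf("<seizure_model> SOP* = %g min, k* = %d feature(s)\n",
              x$sop_star, x$k_star))
  cat("  top features:", paste(utils::head(x$selected_names, 5),
                               collapse = ", "), "\n")
  invisible(x)
}
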