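# The 59 univariate linear features computed per channel per 5-s window.
#
# The feature set covers every family used in patient-specific seizure
# prediction work: relative spectral power in eight bands, all pairwise
# band-power ratios over nine bands (the eight subbands plus a broadband
# gamma composite), the 50% spectral edge frequency and the cumulative
# power at that edge, four statistical moments, the three Hjorth
# parameters, the decorrelation time, and the energies of wavelet detail
# levels D1-D5 (db4). 8 + 36 + 2 + 4 + 3 + 1 + 5 = 59.

RATIO_EPS <- 1e-12

#' The default 59-feature registry
#'
#' An ordered table of the features computed per channel per window. The
#' order is fixed: 8 relative band powers, 36 pairwise band-power ratios
#' (unordered pairs over the 9 bands of [eeg_bands()], numerator earlier in
#' band order), spectral edge frequency at 50% (`sef50`), cumulative power
#' at that edge (`sef50_power`), mean, variance, skewness, kurtosis, Hjorth
#' activity/mobility/complexity, decorrelation time, and wavelet detail
#' energies D1-D5. [extract_features()] accepts any subset/reordering of
#' these names as a replacement registry.
#'
#' @return a `data.frame` with columns `name` and `family`
#'   (spectral/ratio/edge/moment/hjorth/decorrelation/wavelet); 59 rows.
#' @examples
#' nrow(default_registry())
#' table(default_registry()$family)
#' @export
default_registry <- function() {
  bands <- eeg_bands()$name
  rsp <- paste0("rsp_", bands[1:8])
  pairs <- utils::combn(bands, 2)
  ratios <- paste0("ratio_", pairs[1, ], "_", pairs[2, ])
  data.frame(
    name = c(rsp, ratios, "sef50", "sef50_power",
             "mean", "variance", "skewness", "kurtosis",
             "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
             "decorrelation_time",
             paste0("dwt_d", 1:5)),
    family = c(rep("spectral", 8), rep("ratio", 36), rep("edge", 2),
               rep("moment", 4), rep("hjorth", 3), "decorrelation",
               rep("wavelet", 5)),
    stringsAsFactors = FALSE
  )
}

# ---- spectral ---------------------------------------------------------------

# Matrix version used by extract_features(); W is n_windows x samples.
spectral_features_matrix <- function(W, fs, bands = eeg_bands()) {
  p <- welch_psd_matrix(W, fs)
  freq <- p$freq
  f_hi <- min(128, fs / 2)
  total_w <- trap_weights(freq, 0.5, f_hi)
  bw <- vapply(seq_len(nrow(bands)),
               function(i) trap_weights(freq, bands$low[i],
                                        min(bands$high[i], f_hi)),
               numeric(length(freq)))
  total <- as.vector(crossprod(p$psd, total_w))
  bp <- crossprod(p$psd, bw)                     # n_windows x n_bands
  safe_total <- ifelse(total > 0, total, 1)
  rsp <- bp / safe_total
  rsp[total <= 0, ] <- 0

  pairs <- utils::combn(seq_len(nrow(bands)), 2)
  ratios <- rsp[, pairs[1, ], drop = FALSE] /
    (rsp[, pairs[2, ], drop = FALSE] + RATIO_EPS)

  # spectral edge: smallest F with cumulative power from 0.5 Hz >= 50% of total
  Wc <- cell_integral_weights(freq, 0.5, f_hi)
  cells <- crossprod(p$psd, t(Wc))               # n_windows x n_cells
  cum <- t(apply(cells, 1, cumsum))
  if (nrow(W) == 1) cum <- matrix(cum, nrow = 1)
  half <- total / 2
  sef <- rep(0.5, nrow(W))
  for (i in seq_len(nrow(W))) {
    if (total[i] <= 0) next                      # all-zero window: 0.5 Hz floor
    k <- which(cum[i, ] >= half[i] - 1e-15)[1]
    c_prev <- if (k > 1) cum[i, k - 1] else 0
    f_lo_cell <- max(0.5, freq[k])
    f_hi_cell <- min(f_hi, freq[k + 1])
    frac <- if (cells[i, k] > 0) (half[i] - c_prev) / cells[i, k] else 0
    sef[i] <- f_lo_cell + frac * (f_hi_cell - f_lo_cell)
  }
  cbind(rsp = rsp[, 1:8, drop = FALSE], ratios, sef50 = sef,
        sef50_power = half)
}

#' Spectral features of one window
#'
#' Relative band powers, pairwise band-power ratios, the 50% spectral edge
#' frequency, and the cumulative power at that edge, from a Welch PSD
#' (1-s Hann segments, 50% overlap). Relative power is band power divided
#' by total power over 0.5 Hz to `min(128, fs/2)`; band gaps are excluded
#' from numerators but included in the denominator, so the eight relative
#' powers sum to at most 1.
#'
#' @param window numeric vector (one channel, one window).
#' @param fs sampling rate in Hz.
#' @param bands band table as from [eeg_bands()].
#' @return named numeric vector: 8 relative powers, 36 ratios, `sef50`,
#'   `sef50_power`.
#' @export
spectral_features <- function(window, fs, bands = eeg_bands()) {
  v <- drop(spectral_features_matrix(matrix(window, nrow = 1), fs, bands))
  reg <- default_registry()
  names(v) <- reg$name[reg$family %in% c("spectral", "ratio", "edge")]
  v
}

# ---- temporal ---------------------------------------------------------------

temporal_features_matrix <- function(W, fs) {
  n <- ncol(W)
  m <- rowMeans(W)
  Xc <- W - m
  v <- rowMeans(Xc^2)                            # population variance
  ok <- v > 1e-24
  sv <- ifelse(ok, v, 1)
  skew <- ifelse(ok, rowMeans(Xc^3) / sv^1.5, 0)
  kurt <- ifelse(ok, rowMeans(Xc^4) / sv^2, 0)   # Pearson (normal -> 3)

  d1 <- W[, -1, drop = FALSE] - W[, -n, drop = FALSE]
  d2 <- d1[, -1, drop = FALSE] - d1[, -(n - 1), drop = FALSE]
  vd1 <- rowMeans((d1 - rowMeans(d1))^2)
  vd2 <- rowMeans((d2 - rowMeans(d2))^2)
  mob <- ifelse(ok, sqrt(vd1 / sv), 0)
  mob_d <- ifelse(vd1 > 1e-24, sqrt(vd2 / vd1), 0)
  cmx <- ifelse(ok & mob > 0, mob_d / mob, 0)

  dct <- decorrelation_times(Xc, v, fs)
  cbind(mean = m, variance = v, skewness = skew, kurtosis = kurt,
        hjorth_activity = v, hjorth_mobility = mob,
        hjorth_complexity = cmx, decorrelation_time = dct)
}

# Lag (seconds) of the first zero-crossing of the normalized (biased)
# autocorrelation (a 1e-2 tolerance absorbs the finite-window bias of the
# estimator); windows whose autocorrelation never crosses zero get the
# window length. Lags are evaluated incrementally so typical windows stop
# after a few dozen lags.
decorrelation_times <- function(Xc, v, fs) {
  n <- ncol(Xc)
  nw <- nrow(Xc)
  out <- rep(n / fs, nw)
  out[v <= 1e-24] <- 0                           # degenerate (flat) windows
  active <- which(v > 1e-24)
  denom <- n * v
  k <- 1L
  while (length(active) && k < n) {
    r <- rowSums(Xc[active, 1:(n - k), drop = FALSE] *
                 Xc[active, (k + 1):n, drop = FALSE]) / denom[active]
    hit <- r <= 1e-2
    if (any(hit)) {
      out[active[hit]] <- k / fs
      active <- active[!hit]
    }
    k <- k + 1L
  }
  out
}

#' Time-domain features of one window
#'
#' Statistical moments (mean, population variance, skewness, Pearson
#' kurtosis), Hjorth parameters (activity = variance; mobility =
#' `sqrt(var(diff(x))/var(x))` on unscaled first differences; complexity =
#' mobility of the differenced signal divided by mobility of the signal),
#' and the decorrelation time (lag in seconds of the first zero-crossing of
#' the normalized autocorrelation; the window length if no crossing
#' occurs). Degenerate (zero-variance) windows return 0 for
#' skewness/kurtosis/mobility/complexity/decorrelation time.
#'
#' @param window numeric vector of length >= 3.
#' @param fs sampling rate in Hz.
#' @return named numeric vector of 8 values.
#' @export
temporal_features <- function(window, fs) {
  if (length(window) < 3) stop_config("window too short for temporal features")
  drop(temporal_features_matrix(matrix(window, nrow = 1), fs))
}

#' Wavelet detail energies of one window
#'
#' Energies (sums of squared coefficients) of detail levels D1-D5 of a
#' 5-level periodized db4 decomposition.
#'
#' @param window numeric vector, length divisible by 32.
#' @return named numeric vector `dwt_d1` ... `dwt_d5`.
#' @export
wavelet_features <- function(window) {
  en <- as.vector(dwt_detail_energies(matrix(window, nrow = 1)))
  names(en) <- paste0("dwt_d", 1:5)
  en
}

# ---- assembly ---------------------------------------------------------------

#' Extract the per-channel feature matrix from a window set
#'
#' Computes every registry feature for every channel of every window.
#' Columns are grouped by channel (channel blocks in input order), each
#' block holding the registry features in registry order, with
#' channel-qualified names like `"ch01.rsp_alpha"`. Windows containing
#' non-finite samples are dropped with a message.
#'
#' @param window_set a `window_set` from [make_windows()].
#' @param registry a feature registry (default [default_registry()]); any
#'   subset or reordering of the default feature names.
#' @return a `feature_matrix`: `values` (n_windows x n_channels*n_features),
#'   `feature_names`, `keys` (times or segment keys), `registry`, `fs`.
#' @export
extract_features <- function(window_set, registry = default_registry()) {
  w <- window_set$windows
  n_win <- dim(w)[1]
  n_ch <- dim(w)[2]
  fs <- window_set$fs

  keep <- rep(TRUE, n_win)
  for (ch in seq_len(n_ch)) {
    keep <- keep & apply(is.finite(w[, ch, , drop = FALSE]), 1, all)
  }
  if (!all(keep)) {
    message(sum(!keep), " window(s) dropped (non-finite samples)")
    w <- w[keep, , , drop = FALSE]
    n_win <- dim(w)[1]
  }

  chan_names <- sprintf("ch%02d", seq_len(n_ch))
  blocks <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    Wm <- matrix(w[, ch, ], nrow = n_win)
    full <- cbind(
      spectral_features_matrix(Wm, fs),
      temporal_features_matrix(Wm, fs),
      dwt_detail_energies(Wm)
    )
    colnames(full) <- default_registry()$name
    bad <- setdiff(registry$name, colnames(full))
    if (length(bad)) stop_config("unknown registry feature(s): ",
                                 paste(bad, collapse = ", "))
    block <- full[, registry$name, drop = FALSE]
    colnames(block) <- paste(chan_names[ch], registry$name, sep = ".")
    blocks[[ch]] <- block
  }
  values <- do.call(cbind, blocks)

  keys <- if (!is.null(window_set$keys)) {
    window_set$keys[keep, , drop = FALSE]
  } else {
    data.frame(time = window_set$start_times[keep])
  }
  structure(list(
    values = values, feature_names = colnames(values), keys = keys,
    registry = registry, fs = fs, n_channels = n_ch,
    window_length = window_set$window_length,
    seizure_onsets = window_set$seizure_onsets
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d window(s) x %d feature(s) (%d channel(s) x %d)\n",
              nrow(x$values), ncol(x$values), x$n_channels,
              nrow(x$registry)))
  invisible(x)
}
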