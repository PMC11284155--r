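# Welch power spectral density estimation and band-power integration.
#
# Each 5-s window is split into 1-s Hann-tapered segments with 50% overlap
# and the one-sided periodograms are averaged; at a 5-s scale this trades a
# little resolution for a large variance reduction, which matters for
# window-level relative band powers.

hann_window <- function(L) 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))

#' Welch PSD of one signal window
#'
#' @param x numeric vector (one window of one channel).
#' @param fs sampling rate in Hz.
#' @param seg_length segment length in samples (default `fs`, i.e. 1 s).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz, one-sided).
#' @export
welch_psd <- function(x, fs, seg_length = fs, overlap = 0.5) {
  p <- welch_psd_matrix(matrix(x, nrow = 1), fs, seg_length, overlap)
  list(freq = p$freq, psd = drop(p$psd))
}

# Vectorized Welch: W is n_windows x samples; returns psd as
# n_freq x n_windows matrix plus the frequency grid.
welch_psd_matrix <- function(W, fs, seg_length = fs, overlap = 0.5) {
  n <- ncol(W)
  L <- round(seg_length)
  hop <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = hop)
  nseg <- length(starts)
  win <- hann_window(L)
  scale <- 1 / (fs * sum(win^2))
  # columns of M: all segments of window 1, then window 2, ...
  idx <- as.vector(outer(0:(L - 1), starts, `+`))
  M <- matrix(t(W)[idx, , drop = FALSE], nrow = L)
  M <- M * win
  F <- stats::mvfft(M)
  nf <- L %/% 2 + 1L
  P <- (Mod(F[seq_len(nf), , drop = FALSE])^2) * scale
  if (nf > 2) P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]
  dim(P) <- c(nf, nseg, nrow(W))
  psd <- colSums(aperm(P, c(2, 1, 3))) / nseg
  if (nrow(W) == 1) psd <- matrix(psd, ncol = 1)
  list(freq = (0:(nf - 1)) * fs / L, psd = psd)
}

# Trapezoid-rule integration weights over [lo, hi] on the PSD frequency
# grid, with linear interpolation at fractional band edges. band_power =
# t(psd) %*% weights.
trap_weights <- function(freq, lo, hi) {
  w <- numeric(length(freq))
  for (k in seq_len(length(freq) - 1)) {
    f0 <- freq[k]; f1 <- freq[k + 1]
    a <- max(f0, lo); b <- min(f1, hi)
    if (b <= a) next
    m <- (a + b) / 2
    df <- f1 - f0
    w[k] <- w[k] + (b - a) * (f1 - m) / df
    w[k + 1] <- w[k + 1] + (b - a) * (m - f0) / df
  }
  w
}

# Cumulative band power from f_lo up to each grid point (per-cell trapezoid
# integrals clipped below at f_lo), for the spectral-edge search.
cell_integral_weights <- function(freq, lo, hi) {
  ncell <- length(freq) - 1
  Wc <- matrix(0, ncell, length(freq))
  for (k in seq_len(ncell)) {
    f0 <- freq[k]; f1 <- freq[k + 1]
    a <- max(f0, lo); b <- min(f1, hi)
    if (b <= a) next
    m <- (a + b) / 2
    df <- f1 - f0
    Wc[k, k] <- (b - a) * (f1 - m) / df
    Wc[k, k + 1] <- (b - a) * (m - f0) / df
  }
  Wc
}
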