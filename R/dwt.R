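# Periodized discrete wavelet transform with the Daubechies-4 (db4, 8-tap)
# mother wavelet. Periodization keeps the transform exactly orthogonal for
# even input lengths, so detail/approximation energies sum to the input
# energy to machine precision -- the property the wavelet-energy features
# and their tests rely on.

DB4_LO <- c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.18703481171888114,
            -0.02798376941698385, 0.6308807679295904,
            0.7148465705525415, 0.23037781330885523)
DB4_HI <- rev(DB4_LO) * (-1)^(1:8)

# One analysis step on the rows of matrix A (n_signals x len):
# returns list(a, d) each n_signals x len/2. Circular (periodized)
# convolution, downsampled by 2.
dwt_step_rows <- function(A, h, g) {
  len <- ncol(A)
  m <- len %/% 2L
  # column index per output position i (0-based) and tap k: (2i + 4 - k) mod len
  a <- matrix(0, nrow(A), m)
  d <- matrix(0, nrow(A), m)
  base <- 2L * (0:(m - 1L))
  for (k in 0:7) {
    cols <- ((base + 4L - k) %% len) + 1L
    Ak <- A[, cols, drop = FALSE]
    a <- a + h[k + 1] * Ak
    d <- d + g[k + 1] * Ak
  }
  list(a = a, d = d)
}

#' Periodized db4 wavelet decomposition
#'
#' @param x numeric vector whose length is divisible by `2^levels`.
#' @param levels number of decomposition levels (default 5).
#' @return list with `details` (list of detail-coefficient vectors, level 1
#'   first) and `approx` (final approximation coefficients).
#' @export
dwt_db4 <- function(x, levels = 5) {
  n <- length(x)
  if (n < 2^levels) stop_config("window too short for ", levels, "-level DWT")
  if (n %% 2^levels != 0) {
    stop_config("window length must be divisible by 2^levels for periodized DWT")
  }
  A <- matrix(x, nrow = 1)
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    s <- dwt_step_rows(A, DB4_LO, DB4_HI)
    details[[lev]] <- drop(s$d)
    A <- s$a
  }
  list(details = details, approx = drop(A))
}

# Vectorized detail energies for many windows at once: W is
# n_windows x samples; returns n_windows x levels matrix of detail
# energies, plus approximation energy (for conservation checks).
dwt_detail_energies <- function(W, levels = 5) {
  n <- ncol(W)
  if (n < 2^levels) stop_config("window too short for ", levels, "-level DWT")
  if (n %% 2^levels != 0) {
    stop_config("window length must be divisible by 2^levels for periodized DWT")
  }
  en <- matrix(0, nrow(W), levels)
  A <- W
  for (lev in seq_len(levels)) {
    s <- dwt_step_rows(A, DB4_LO, DB4_HI)
    en[, lev] <- rowSums(s$d^2)
    A <- s$a
  }
  attr(en, "approx_energy") <- rowSums(A^2)
  en
}
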