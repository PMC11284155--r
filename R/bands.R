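#' EEG frequency band definitions
#'
#' The fixed set of frequency bands used throughout the feature extractor:
#' delta (0.5--4 Hz), theta (4--8 Hz), alpha (8--13 Hz), beta (13--30 Hz),
#' four gamma subbands -- gamma1 (30--47 Hz), gamma2 (53--75 Hz),
#' gamma3 (75--97 Hz), gamma4 (103--128 Hz) -- and a broadband gamma
#' composite (30--128 Hz) used only in band-power ratios. The gaps at
#' 47--53 Hz and 97--103 Hz keep mains interference and its first harmonic
#' out of every band, which is why no separate notch filter is applied.
#'
#' @param include_broadband if `TRUE` (default) append the broadband gamma
#'   composite as a ninth row; the eight subbands alone are used for
#'   relative-power features, all nine for the pairwise ratios.
#' @return a `data.frame` with columns `name`, `low`, `high` (Hz), in the
#'   fixed band order used for feature naming.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function(include_broadband = TRUE) {
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta",
             "gamma1", "gamma2", "gamma3", "gamma4"),
    low  = c(0.5, 4, 8, 13, 30, 53, 75, 103),
    high = c(4, 8, 13, 30, 47, 75, 97, 128),
    stringsAsFactors = FALSE
  )
  if (include_broadband) {
    b <- rbind(b, data.frame(name = "gamma", low = 30, high = 128))
  }
  b
}
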