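#' Frequency band definitions
#'
#' The eight canonical bands used throughout the pre-stimulus EEG pipeline:
#' delta (1--4 Hz), theta (5--7), low alpha (8--10), high alpha (11--13),
#' low beta (14--21), high beta (22--30), low gamma (31--50) and high gamma
#' (51--80). Band edges are inclusive integer-Hz bins at the 1 Hz
#' resolution of the Welch estimator, so the eight bands partition the
#' analyzed 1--80 Hz range exactly. The sub-1 Hz part of the conventional
#' delta band is unresolvable in a 1.5 s epoch, hence delta starts at 1 Hz.
#'
#' @return A data frame with columns `band`, `lo`, `hi` (Hz, inclusive).
#' @export
#' @examples
#' band_definitions()
band_definitions <- function() {
  data.frame(
    band = c("delta", "theta", "low_alpha", "high_alpha",
             "low_beta", "high_beta", "low_gamma", "high_gamma"),
    lo = c(1, 5, 8, 11, 14, 22, 31, 51),
    hi = c(4, 7, 10, 13, 21, 30, 50, 80),
    stringsAsFactors = FALSE
  )
}

band_names <- function() band_definitions()$band

## Membership map: for each analyzed bin (1..80 Hz) the band it belongs to.
band_of_bin <- function(freqs = 1:80) {
  bd <- band_definitions()
  idx <- rep(NA_integer_, length(freqs))
  for (j in seq_len(nrow(bd))) {
    idx[freqs >= bd$lo[j] & freqs <= bd$hi[j]] <- j
  }
  idx
}
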