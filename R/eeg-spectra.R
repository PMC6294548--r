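## Welch periodogram --------------------------------------------------------
##
## Settings are fixed to the epoch geometry of the paradigm: 1.5 s epochs at
## 1000 Hz, averaged over 1.0 s Hann-tapered segments with 50 % overlap
## (two segments per epoch), giving 1 Hz bins. The estimator is normalized
## so that the one-sided power sum over all positive bins equals the signal
## power (Parseval): a unit-amplitude tone carries ~A^2/2 = 0.5 in its band.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Welch power spectrum of one epoch channel
#'
#' Averaged modified periodogram with Hann-tapered segments. Defaults give
#' 1 Hz resolution on a 1.5 s, 1000 Hz epoch (two half-overlapping 1 s
#' segments). Power is normalized so the sum over positive-frequency bins
#' estimates total signal power.
#'
#' @param x numeric vector (one channel of one epoch), or a matrix with one
#'   epoch per column.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @param overlap fractional segment overlap.
#' @return A list with `freq` (Hz, 0..fs/2) and `power` (same length;
#'   a matrix with one column per epoch if `x` was a matrix).
#' @export
#' @examples
#' t <- seq(0, 1.499, by = 1e-3)
#' sp <- welch_spectrum(sin(2 * pi * 20 * t))
#' sp$freq[which.max(sp$power)]  # 20
welch_spectrum <- function(x, fs = 1000, nperseg = 1000, overlap = 0.5) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  n <- nrow(xm)
  if (n < nperseg) stop("epoch shorter than one Welch segment")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  norm <- 2 / (nperseg * sum(w^2))
  nf <- nperseg %/% 2 + 1L
  acc <- matrix(0, nf, ncol(xm))
  for (s in starts) {
    seg <- xm[s:(s + nperseg - 1L), , drop = FALSE] * w
    ft <- stats::mvfft(seg)
    acc <- acc + (Mod(ft[seq_len(nf), , drop = FALSE])^2) * norm
  }
  pw <- acc / length(starts)
  ## DC and Nyquist are not doubled by the one-sided convention
  pw[1, ] <- pw[1, ] / 2
  if (nperseg %% 2 == 0) pw[nf, ] <- pw[nf, ] / 2
  freq <- (seq_len(nf) - 1L) * fs / nperseg
  list(freq = freq,
       power = if (is.matrix(x)) pw else drop(pw))
}

## Expected Welch response of a unit-amplitude cosine at frequency f0,
## averaged over phase (deterministic probe used by the generator's
## effect-size calibration). Returns power over integer bins 1..80 Hz.
tone_welch_profile <- function(f0, fs = 1000, n = 1500, nperseg = 1000,
                               overlap = 0.5, fmax = 80) {
  t <- (seq_len(n) - 1) / fs
  phases <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  acc <- 0
  for (ph in phases) {
    sp <- welch_spectrum(cos(2 * pi * f0 * t + ph), fs, nperseg, overlap)
    acc <- acc + sp$power[2:(fmax + 1)]
  }
  acc / length(phases)
}

## Expected Welch spectrum (bins 1..fmax Hz) of the randomized-phase 1/f
## background whose synthesis-line powers are `line_power` at frequencies
## `line_freq` (both on the 1.5 s epoch grid). Exact expectation over the
## random phases: each line contributes its power smeared by the squared
## window transfer evaluated at the bin-line frequency offset.
background_welch_profile <- function(line_freq, line_power, fs = 1000,
                                     nperseg = 1000, overlap = 0.5,
                                     fmax = 80) {
  w <- hann_window(nperseg)
  pad <- 3L                                  # 1/3 Hz transfer grid
  W <- stats::fft(c(w, rep(0, (pad - 1) * nperseg)))
  W2 <- Mod(W)^2
  ngrid <- length(W2)
  norm <- 2 / (nperseg * sum(w^2))
  out <- numeric(fmax)
  df_grid <- fs / (pad * nperseg)
  for (b in seq_len(fmax)) {
    delta <- b - line_freq
    idx <- round(abs(delta) / df_grid) %% ngrid + 1L
    ## amplitude a with power p = a^2/2 -> |X(b)| ~ (a/2)|W(delta)|
    out[b] <- sum(line_power / 2 * W2[idx]) * norm
  }
  out
}
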