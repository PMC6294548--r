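## State-dependent EEG epoch generator ---------------------------------------
##
## Each channel of a 1.5 s pre-pulse epoch is the sum of a randomized-phase
## 1/f background (fixed spectral moduli) and one constant-envelope
## oscillator per band, with random phase and log-normal amplitude jitter.
## The UP/DOWN state shifts each oscillator's log-amplitude by +/- Delta/2.
##
## Because band power is an analytic function of the eight log-amplitudes,
## the shift vector Delta that realizes prescribed standardized effect
## sizes (band_d) on *relative* band power is solved at construction rather
## than tuned: first and second moments of relative band power under the
## shift are computed from the power map with a fixed-seed internal Monte
## Carlo (exact under the log-normal amplitude law), the Welch estimation
## noise is measured once from a deterministic zero-jitter probe, and the
## shift is found by Newton iteration on the resulting mean-difference map.
##
## Compositional closure: the 8 bands partition the analyzed 1-80 Hz range,
## so UP-DOWN differences of relative power must sum to zero, while the
## prescribed d_j and the bands' SDs s_j need not satisfy sum(d_j s_j) = 0.
## The generator restores consistency by scaling the amplitude variability
## of the negative-effect bands (a free realism parameter) until
## sum(d_j s_j) = 0; if the sign pattern of band_d makes that impossible,
## the residual is spread in least-squares fashion across bands instead.

EEG_N <- 1500L
EEG_FS <- 1000L

.meploop_cache <- new.env(parent = emptyenv())

## Run code under a private RNG stream, leaving the caller's untouched.
with_private_seed <- function(seed, fun) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

eeg_calibration <- function(p) {
  key <- paste(c(p$band_d, p$osc_freqs, p$one_over_f_exponent, p$osc_snr,
                 p$band_sigma, p$subject_het, p$eeg_bg_power,
                 p$band_noise_cor),
               collapse = "|")
  hit <- .meploop_cache[[key]]
  if (!is.null(hit)) return(hit)
  cal <- with_private_seed(20260921L, function() eeg_calibration_impl(p))
  .meploop_cache[[key]] <- cal
  cal
}

eeg_calibration_impl <- function(p) {
  nb <- 8L
  d <- unname(p$band_d)
  ## --- synthesis lines of the 1/f background on the 1.5 s grid
  kline <- seq_len(EEG_N %/% 2 - 1L)          # exclude DC and Nyquist
  f_line <- kline * EEG_FS / EEG_N
  raw <- pmax(f_line, 1)^(-p$one_over_f_exponent)
  scale <- p$eeg_bg_power / sum(raw[f_line >= 1 & f_line <= 80])
  p_line <- raw * scale
  a_line <- sqrt(2 * p_line)
  ## --- expected Welch responses
  bgW <- background_welch_profile(f_line, p_line)
  bin_band <- band_of_bin(1:80)
  Bg <- as.numeric(tapply(bgW, bin_band, sum))
  C <- t(vapply(p$osc_freqs, tone_welch_profile, numeric(80)))  # osc x bin
  Cmat <- t(apply(C, 1, function(r) tapply(r, bin_band, sum)))  # osc x band
  a0 <- sqrt(2 * p$osc_snr * Bg)
  cal <- list(f_line = f_line, a_line = a_line, a0 = a0,
              Bg = Bg, Cmat = Cmat, rho = p$band_noise_cor)
  ## --- Welch estimation noise from a deterministic zero-jitter probe
  nprobe <- 400L
  xp <- synth_epochs_channel(nprobe, rep(0, nprobe), rep(0, nb),
                             cal, rep(0, nb), p$osc_freqs)
  relp_probe <- epoch_band_relpower(xp)
  v_meas <- apply(relp_probe, 1, stats::var)
  ## --- moments of relative band power under a shift, via the power map
  nmc <- 8000L
  rho <- p$band_noise_cor
  EPS <- matrix(stats::rnorm(nmc * nb), nmc, nb)
  G <- stats::rnorm(nmc)
  EPS <- sqrt(rho) * G + sqrt(1 - rho) * EPS   # shared arousal factor
  EPS <- rbind(EPS, -EPS)                      # antithetic
  moments <- function(Delta, sig) {
    one <- function(sgn) {
      Z <- sweep(sweep(EPS, 2, sig, `*`), 2, sgn * Delta / 2, `+`)
      X <- sweep(exp(2 * Z), 2, a0^2, `*`)
      B <- sweep(X %*% Cmat, 2, Bg, `+`)
      relP <- 100 * B / rowSums(B)
      list(m = colMeans(relP), v = apply(relP, 2, stats::var))
    }
    up <- one(1); dn <- one(-1)
    list(diff = up$m - dn$m,
         s = sqrt((up$v + dn$v) / 2 + v_meas))
  }
  ## --- null model: no effect anywhere, shift is exactly zero
  if (all(d == 0)) {
    mom0 <- moments(rep(0, nb), rep_len(p$band_sigma, nb))
    cal$sigma_vec <- rep_len(p$band_sigma, nb)
    cal$Delta <- rep(0, nb)
    cal$Jinv <- diag(nb)
    cal$s <- mom0$s
    cal$m <- rep(0, nb)
    cal$v_meas <- v_meas
    cal$tau <- rep(0, nb)
    return(cal)
  }
  ## --- compositional closure through per-band amplitude variability
  sig0 <- rep_len(p$band_sigma, nb)
  neg <- d < 0
  pos <- d > 0
  sig_of <- function(rr) ifelse(neg, sig0 * rr, sig0)
  closure <- function(rr) sum(d * moments(rep(0, nb), sig_of(rr))$s)
  sig <- sig0
  if (any(neg) && any(pos)) {
    lo <- closure(0.25); hi <- closure(4)
    if (sign(lo) != sign(hi)) {
      rr <- stats::uniroot(closure, c(0.25, 4), tol = 1e-3)$root
      sig <- sig_of(rr)
    }
  }
  ## --- Newton solve for the shift vector
  mom0 <- moments(rep(0, nb), sig)
  s <- mom0$s
  m <- d * s
  m <- m - s * (sum(m) / sum(s))               # residual (if any) spread LS
  Jn <- matrix(0, nb, nb)                      # numeric Jacobian of diff map
  h <- 0.05
  for (k in seq_len(nb)) {
    e <- rep(0, nb); e[k] <- h
    Jn[, k] <- (moments(e, sig)$diff - moments(-e, sig)$diff) / (2 * h)
  }
  Jinv <- MASS::ginv(Jn)
  Delta <- as.numeric(Jinv %*% m)
  for (it in 1:6) {
    mo <- moments(Delta, sig)
    m <- d * mo$s
    m <- m - mo$s * (sum(m) / sum(mo$s))
    Delta <- Delta + as.numeric(Jinv %*% (m - mo$diff))
  }
  ## --- one empirical correction pass through the actual synthesis and
  ## Welch pipeline (fixed private seed): absorbs what the analytic
  ## moment model misses (amplitude-dependent estimation noise)
  nemp <- 2500L
  for (it in 1:2) {
    bp_up <- epoch_band_relpower(synth_epochs_channel(
      nemp, rep(1, nemp), Delta, cal, sig, p$osc_freqs))
    bp_dn <- epoch_band_relpower(synth_epochs_channel(
      nemp, rep(-1, nemp), Delta, cal, sig, p$osc_freqs))
    s_emp <- sqrt((apply(bp_up, 1, stats::var) +
                     apply(bp_dn, 1, stats::var)) / 2)
    m_t <- d * s_emp
    m_t <- m_t - s_emp * (sum(m_t) / sum(s_emp))
    diff_emp <- rowMeans(bp_up) - rowMeans(bp_dn)
    Delta <- Delta + as.numeric(Jinv %*% (m_t - diff_emp))
  }
  mo <- list(s = s_emp, diff = m_t)
  cal$sigma_vec <- sig
  cal$Delta <- Delta
  cal$Jinv <- Jinv
  cal$s <- mo$s
  cal$m <- mo$diff
  cal$v_meas <- v_meas
  cal$tau <- p$subject_het * mo$s * sqrt(8 / 7)  # sqrt(8/7): subject offsets
                                                 # are re-centered by the solve
  cal
}

## Relative band power (8 x n_epochs, %) of an epoch matrix, by the same
## Welch pipeline the analysis side uses.
epoch_band_relpower <- function(x) {
  sp <- welch_spectrum(x)
  pw <- sp$power[2:81, , drop = FALSE]
  relp <- 100 * sweep(pw, 2, colSums(pw), `/`)
  bb <- band_of_bin(1:80)
  apply(relp, 2, function(col) as.numeric(tapply(col, bb, sum)))
}

#' Draw a subject-specific band-shift vector
#'
#' Adds between-subject heterogeneity to the calibrated UP-vs-DOWN band
#' shift: the subject's target mean difference of relative band power is
#' the cohort mean plus a zero-mean Gaussian deviation with SD
#' `subject_het` times the within-subject epoch SD, mapped back to
#' log-amplitude shifts through the calibration Jacobian.
#'
#' @param params a [participant_params()].
#' @return Length-8 log-amplitude shift vector for this subject.
#' @export
draw_subject_shift <- function(params) {
  cal <- params$eeg_cal
  zeta <- stats::rnorm(8, 0, cal$tau)
  as.numeric(cal$Delta + cal$Jinv %*% zeta)
}

## Vectorized epoch synthesis for one channel. `sgn` is the per-epoch
## signed shift multiplier (+1 UP, -1 DOWN, 0 REST, already scaled by
## skill); `delta` the band-shift vector (already channel-attenuated).
synth_epochs_channel <- function(n_epochs, sgn, delta, cal, sigma_vec,
                                 osc_freqs) {
  nline <- length(cal$a_line)
  ph <- matrix(stats::runif(nline * n_epochs, 0, 2 * pi), nline, n_epochs)
  coef <- matrix(0+0i, EEG_N, n_epochs)
  coef[1 + seq_len(nline), ] <- cal$a_line * exp(1i * ph)
  x <- Re(stats::mvfft(coef, inverse = TRUE))
  t_sec <- (seq_len(EEG_N) - 1) / EEG_FS
  g <- stats::rnorm(n_epochs)                  # shared arousal factor
  rho <- cal$rho
  for (j in 1:8) {
    eps <- sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(n_epochs)
    A <- exp(log(cal$a0[j]) + sgn * delta[j] / 2 + sigma_vec[j] * eps)
    phi <- stats::runif(n_epochs, 0, 2 * pi)
    cvec <- cos(2 * pi * osc_freqs[j] * t_sec)
    svec <- sin(2 * pi * osc_freqs[j] * t_sec)
    x <- x + cvec %o% (A * cos(phi)) - svec %o% (A * sin(phi))
  }
  x
}

#' Generate state-dependent pre-pulse EEG epochs
#'
#' Synthesizes 1.5 s multichannel epochs at 1000 Hz: a 1/f background plus
#' one band-limited oscillator per frequency band. At the hotspot channel
#' the oscillators' log amplitudes are shifted by half the calibrated
#' band-shift vector, signed by the epoch's strategy and scaled by the
#' learned skill; other channels carry the shift attenuated by
#' `offhot_atten`.
#'
#' @param state a [latent_state()]; its strategy and skills set the shift.
#' @param params a [participant_params()].
#' @param n_epochs number of epochs to draw.
#' @param n_channels number of EEG channels.
#' @param hotspot_index channel closest to the TMS hotspot.
#' @param strategy optional per-epoch strategy vector overriding
#'   `state$strategy` (mix conditions in one call).
#' @param subject_shift optional subject-specific shift vector from
#'   [draw_subject_shift()]; defaults to the cohort-mean calibrated shift.
#' @return An object of class `eeg_epochs`: list with `data` (one
#'   samples-by-epochs matrix per channel), `strategy`, `hotspot`, `fs`.
#' @export
#' @examples
#' p <- participant_params()
#' st <- latent_state("UP", skill_up = 1, params = p)
#' ep <- generate_eeg_epoch(st, p, n_epochs = 4)
#' dim(ep$data[[1]])
generate_eeg_epoch <- function(state, params, n_epochs = 1, n_channels = 1,
                               hotspot_index = 1, strategy = NULL,
                               subject_shift = NULL) {
  stopifnot(n_channels >= 1, hotspot_index >= 1,
            hotspot_index <= n_channels)
  strat <- rep_len(strategy %||% state$strategy, n_epochs)
  sgn <- ifelse(strat == "UP", 1, ifelse(strat == "DOWN", -1, 0))
  skill <- ifelse(strat == "UP", state$skill_up,
                  ifelse(strat == "DOWN", state$skill_down, 0))
  cal <- params$eeg_cal
  delta0 <- subject_shift %||% cal$Delta
  chans <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    atten <- if (ch == hotspot_index) 1 else params$offhot_atten
    chans[[ch]] <- synth_epochs_channel(
      n_epochs, sgn * skill, delta0 * atten, cal, cal$sigma_vec,
      params$osc_freqs)
  }
  structure(list(data = chans, strategy = strat, hotspot = hotspot_index,
                 fs = EEG_FS), class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d channel(s) x %d samples x %d epochs @ %d Hz, hotspot ch %d\n",
    length(x$data), nrow(x$data[[1]]), ncol(x$data[[1]]), x$fs, x$hotspot))
  invisible(x)
}
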