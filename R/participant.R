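## participant_model: generative model of one synthetic subject ------------
##
## A latent corticomotor excitability multiplier acts on the *effective
## stimulus intensity* of a sigmoid recruitment curve, so that volitional
## up-regulation saturates at the recruitment plateau. Operant learning
## accrues skill on veridically rewarded trials only; EEG epochs carry
## band-limited oscillations whose log-amplitude is shifted between the UP
## and DOWN states so that relative band power separates at prescribed
## standardized effect sizes.

#' Generative parameters of a synthetic participant
#'
#' Returns the full set of constants that define one synthetic subject.
#' Defaults are calibrated so that a cohort run through the default
#' closed-loop protocol reproduces the trained group effects this model is
#' built around: ~+83.8 % (UP) and ~-30.6 % (DOWN) change of MEP amplitude
#' from baseline, per-band relative-power effect sizes `band_d`, and
#' late-cortical-disinhibition gains of +50.9 (UP vs rest) and -5.2
#' (DOWN vs rest) percentage points.
#'
#' @param rmt resting motor threshold, % maximal stimulator output.
#' @param i50 intensity at half-maximal MEP (% output); default 130 % RMT.
#' @param slope_k recruitment sigmoid steepness (per % output). The default
#'   places a ~0.05 mV mean MEP at RMT.
#' @param mep_max maximal MEP amplitude (mV).
#' @param mep_noise_cv coefficient of variation of the multiplicative
#'   log-normal MEP noise.
#' @param emg_rest_rms resting EMG rms per muscle (uV; recycled to 4).
#' @param up_asymptote,down_asymptote maximal attainable excitability
#'   multipliers. `NULL` (default) calibrates them so the expected trained
#'   percent change from baseline under the default calibration protocol
#'   equals `target_up_pct` / `-target_down_pct`.
#' @param target_up_pct,target_down_pct trained group effects (percent
#'   change from baseline) the asymptote calibration aims at.
#' @param learn_rate skill increment per veridically rewarded trial.
#' @param retention_frac fraction of skill retained at long-term follow-up.
#' @param coupling interhemispheric spillover of the excitability deviation.
#' @param band_d signed standardized UP-vs-DOWN effect sizes on relative
#'   band power (length 8, band order of [band_definitions()]).
#' @param osc_freqs oscillator center frequency per band (Hz).
#' @param one_over_f_exponent spectral slope of the EEG background.
#' @param osc_snr in-band oscillator-to-background power ratio.
#' @param band_sigma SD of the per-epoch log-amplitude jitter of each band
#'   oscillator.
#' @param subject_het between-subject heterogeneity of the band shift, as a
#'   fraction of the within-subject epoch SD of relative band power.
#' @param band_noise_cor fraction of each band's log-amplitude jitter
#'   variance carried by a shared (arousal-like) factor; the cross-band
#'   noise correlation. Per-band effect sizes leave this unconstrained, so
#'   its default is calibrated against the study's printed decoding
#'   accuracy.
#' @param offhot_atten attenuation of the band shift on non-hotspot
#'   channels.
#' @param eeg_bg_power total background EEG power over 1--80 Hz (uV^2).
#' @param excit_jitter_sd SD of the zero-mean trial-to-trial excitability
#'   jitter.
#' @param sici_ratio,lici_ratio conditioned/test ratios at rest when a
#'   protocol carries no explicit conditioning intensity.
#' @param sici_cs_mid,sici_cs_width,sici_inh_max,lici_cs_mid,lici_cs_width,lici_inh_max
#'   logistic map from conditioning-stimulus intensity (% RMT) to
#'   inhibition depth, used by the conditioning-stimulus search.
#' @param lcd_gain_up,lcd_gain_down additive late-cortical-disinhibition
#'   gain (percentage points of the single-pulse MEP) in the trained UP /
#'   DOWN state.
#' @param p_tense probability that a trial contains a transient muscle
#'   tension episode (re-arming the EMG gate).
#' @param seed RNG seed identifying the participant.
#' @return An object of class `participant_params`.
#' @export
participant_params <- function(rmt = 40,
                               i50 = 1.3 * rmt,
                               slope_k = log(4 / 0.05 - 1) / (i50 - rmt),
                               mep_max = 4,
                               mep_noise_cv = 0.15,
                               emg_rest_rms = 4,
                               up_asymptote = NULL,
                               down_asymptote = NULL,
                               target_up_pct = 83.8,
                               target_down_pct = 30.6,
                               learn_rate = 0.02,
                               retention_frac = 0.8,
                               coupling = 0.35,
                               band_d = c(delta = 0.754, theta = -0.947,
                                          low_alpha = -0.805,
                                          high_alpha = -0.714,
                                          low_beta = 0, high_beta = 0,
                                          low_gamma = 0.753,
                                          high_gamma = 0.712),
                               osc_freqs = c(2.5, 6, 9, 12, 17.5, 26, 40, 65),
                               one_over_f_exponent = 1.5,
                               osc_snr = 6,
                               band_sigma = 0.3,
                               subject_het = 0.2,
                               band_noise_cor = 0.6,
                               offhot_atten = 0.5,
                               eeg_bg_power = 200,
                               excit_jitter_sd = 0.01,
                               sici_ratio = 0.5,
                               lici_ratio = 0.5,
                               sici_cs_mid = 74, sici_cs_width = 6,
                               sici_inh_max = 0.85,
                               lici_cs_mid = 109, lici_cs_width = 3,
                               lici_inh_max = 0.9,
                               lcd_gain_up = 50.9,
                               lcd_gain_down = -5.2,
                               p_tense = 0.04,
                               seed = 1L) {
  stopifnot(mep_max > 0, mep_noise_cv >= 0, rmt > 0, i50 > rmt,
            slope_k > 0, length(band_d) == 8, length(osc_freqs) == 8,
            retention_frac >= 0, retention_frac <= 1,
            coupling >= 0, coupling <= 1)
  names(band_d) <- band_names()
  if (is.null(up_asymptote) || is.null(down_asymptote)) {
    asym <- calibrate_asymptotes(rmt, i50, slope_k, mep_noise_cv,
                                 target_up_pct, target_down_pct,
                                 jitter_sd = excit_jitter_sd)
    if (is.null(up_asymptote)) up_asymptote <- asym$up
    if (is.null(down_asymptote)) down_asymptote <- asym$down
  }
  stopifnot(down_asymptote > 0, down_asymptote < 1, up_asymptote > 1)
  p <- list(rmt = rmt, i50 = i50, slope_k = slope_k, mep_max = mep_max,
            mep_noise_cv = mep_noise_cv,
            emg_rest_rms = rep_len(emg_rest_rms, 4),
            up_asymptote = up_asymptote, down_asymptote = down_asymptote,
            learn_rate = learn_rate, retention_frac = retention_frac,
            coupling = coupling, band_d = band_d, osc_freqs = osc_freqs,
            one_over_f_exponent = one_over_f_exponent, osc_snr = osc_snr,
            band_sigma = band_sigma, subject_het = subject_het,
            band_noise_cor = band_noise_cor,
            offhot_atten = offhot_atten, eeg_bg_power = eeg_bg_power,
            excit_jitter_sd = excit_jitter_sd,
            sici_ratio = sici_ratio, lici_ratio = lici_ratio,
            sici_cs_mid = sici_cs_mid, sici_cs_width = sici_cs_width,
            sici_inh_max = sici_inh_max,
            lici_cs_mid = lici_cs_mid, lici_cs_width = lici_cs_width,
            lici_inh_max = lici_inh_max,
            lcd_gain_up = lcd_gain_up, lcd_gain_down = lcd_gain_down,
            p_tense = p_tense, seed = as.integer(seed))
  p$eeg_cal <- eeg_calibration(p)
  class(p) <- "participant_params"
  p
}

#' @export
print.participant_params <- function(x, ...) {
  cat("<participant_params>\n")
  cat(sprintf("  RMT %.1f %%MSO, I50 %.1f, k %.3f, MEPmax %.2f mV (CV %.2f)\n",
              x$rmt, x$i50, x$slope_k, x$mep_max, x$mep_noise_cv))
  cat(sprintf("  asymptotes: UP %.4f / DOWN %.4f, learn_rate %.3f\n",
              x$up_asymptote, x$down_asymptote, x$learn_rate))
  cat(sprintf("  band_d: %s\n",
              paste(sprintf("%+.2f", x$band_d), collapse = " ")))
  invisible(x)
}

## Calibration of the excitability asymptotes at the ideal operating point
## (test intensity = i50, baseline at half the plateau): the asymptote is
## solved so that the jitter-averaged recruitment mean at full skill sits
## target_up / target_down percent away from the jitter-averaged baseline.
## Per-participant recalibration against the *realized* calibration is
## available via recalibrate_asymptotes().
calibrate_asymptotes <- function(rmt, i50, k, cv,
                                 target_up_pct = 83.8,
                                 target_down_pct = 30.6,
                                 jitter_sd = 0.01) {
  curve_at <- function(a) {
    gh_expect(function(e) stats::plogis(k * i50 * (a + e) - k * i50),
              jitter_sd)
  }
  base <- curve_at(1)
  up <- stats::uniroot(function(a) {
    curve_at(a) - min((1 + target_up_pct / 100) * base, 0.9975)
  }, c(1 + 1e-9, 6))$root
  down <- stats::uniroot(function(a) {
    curve_at(a) - (1 - target_down_pct / 100) * base
  }, c(0.05, 1 - 1e-9))$root
  list(up = up, down = down)
}

## Gauss-Hermite expectation of f(e), e ~ N(0, sd) (7 nodes).
gh_expect <- function(f, sd) {
  x <- c(0, 0.8162878829, -0.8162878829, 1.6735516288, -1.6735516288,
         2.6519613568, -2.6519613568)
  w <- c(0.8102646176, 0.4256072526, 0.4256072526, 0.0545155828,
         0.0545155828, 0.0009717812, 0.0009717812)
  sum(w / sqrt(pi) * vapply(sqrt(2) * sd * x, f, numeric(1)))
}

#' Calibrate the asymptotes to a participant's measured operating point
#'
#' Re-expresses the attainable modulation range relative to the
#' participant's own realized calibration: the asymptotes are solved so
#' that the *expected measured* percent change from the session baseline
#' at full skill equals the group targets, given the test intensity the
#' calibration actually chose. The expectation integrates the
#' trial-to-trial excitability jitter (Gauss-Hermite quadrature); on the
#' UP side the attainable mean is capped just below the recruitment
#' plateau (the cap binds only when the calibrated baseline landed well
#' above half the plateau).
#'
#' The calibration targets the percent change as the offline pipeline
#' measures it: deterministic factors for block trimming (expected
#' trimmed-mean of a log-normal sample, 30-trial feedback vs 20-trial
#' baseline blocks) and for the upper interquartile fence (which clips
#' the right tail of the highest-amplitude condition) are folded into the
#' solve.
#'
#' @param params a [participant_params()].
#' @param cal the participant's `calibration_result`.
#' @param target_up_pct,target_down_pct group-level percent changes.
#' @return `params` with `up_asymptote` and `down_asymptote` replaced.
#' @export
recalibrate_asymptotes <- function(params, cal, target_up_pct = 83.8,
                                   target_down_pct = 30.6) {
  k <- params$slope_k; i50 <- params$i50
  I <- cal$test_intensity; sdj <- params$excit_jitter_sd
  curve_at <- function(a) {
    gh_expect(function(e) stats::plogis(k * (I * (a + e) - i50)), sdj)
  }
  base_rel <- curve_at(1)
  sig_ln <- sqrt(log(1 + params$mep_noise_cv^2))
  ## per-condition total log-scale SD (amplitude noise + excitability
  ## jitter through the local log-slope of the recruitment curve)
  sig_at <- function(p_rel) {
    sqrt(sig_ln^2 + (k * I * (1 - p_rel) * sdj)^2)
  }
  sig_b <- sig_at(base_rel)
  kappa_b <- trimmed_mean_factor(20, sig_b)
  p_at_skill <- function(a, sk) {
    gh_expect(function(e) {
      stats::plogis(k * (I * (1 + sk * (a - 1) + e) - i50))
    }, sdj)
  }
  ## DOWN first (no fence interaction); its level feeds the pool model
  target_dn_rel <- (1 - target_down_pct / 100) * base_rel
  params$down_asymptote <- stats::uniroot(function(a) {
    p <- curve_at(a)
    p * trimmed_mean_factor(30, sig_at(p)) / kappa_b - target_dn_rel
  }, c(0.05, 1 - 1e-9))$root
  p_dn <- curve_at(params$down_asymptote)
  ## measured/true mean ratio of the trained UP condition after trimming
  ## and the subject-pool interquartile fence; the pool mixes resting
  ## blocks, first-day learning-ramp trials (average skill ~ 0.5) and
  ## trained trials of both directions
  up_chain <- function(a) {
    p_up <- curve_at(a)
    sig_u <- sig_at(p_up)
    lev <- c(base_rel, p_at_skill(a, 0.65), p_up,
             p_at_skill(params$down_asymptote, 0.65), p_dn)
    wts <- c(360, 120, 180, 120, 180) / 960
    sigs <- c(sig_b, sig_at(lev[2]), sig_u, sig_at(lev[4]), sig_at(p_dn))
    qmix <- function(q) {
      stats::uniroot(function(x) {
        sum(wts * stats::plnorm(x, log(lev) - sigs^2 / 2, sigs)) - q
      }, c(1e-4, 10))$root
    }
    q1 <- qmix(0.25); q3 <- qmix(0.75)
    fence <- q3 + 1.5 * (q3 - q1)
    z <- (log(fence) - (log(p_up) - sig_u^2 / 2)) / sig_u
    iqr_fac <- stats::pnorm(z - sig_u) / stats::pnorm(z)
    trimmed_mean_factor(30, sig_u) * iqr_fac
  }
  target_up_rel <- min((1 + target_up_pct / 100) * base_rel, 0.9975)
  f_up <- function(a) {
    curve_at(a) * up_chain(a) / kappa_b - target_up_rel
  }
  params$up_asymptote <- if (f_up(6) < 0) 6 else
    stats::uniroot(f_up, c(1 + 1e-9, 6))$root
  params
}

## Expected mean of a mean-1 log-normal sample of size n after removing
## its maximum and minimum, relative to the untrimmed mean.
trimmed_mean_factor <- function(n, sig) {
  f <- function(x) exp(sig * x - sig^2 / 2) * stats::dnorm(x)
  emax <- stats::integrate(function(x) n * f(x) * stats::pnorm(x)^(n - 1),
                           -8, 8)$value
  emin <- stats::integrate(function(x) {
    n * f(x) * (1 - stats::pnorm(x))^(n - 1)
  }, -8, 8)$value
  (n - emax - emin) / (n - 2)
}

## Latent state --------------------------------------------------------------

#' Latent excitability state
#'
#' @param strategy one of `"UP"`, `"DOWN"`, `"REST"`.
#' @param skill_up,skill_down learned modulation skill in \[0, 1\].
#' @param excitability current excitability multiplier (1 = resting
#'   baseline). Defaults to the strategy's expected value.
#' @param params a [participant_params()] object (used for the default
#'   excitability).
#' @return An object of class `latent_state`.
#' @export
latent_state <- function(strategy = "REST", skill_up = 0, skill_down = 0,
                         excitability = NULL, params = NULL) {
  strategy <- match.arg(strategy, c("UP", "DOWN", "REST"))
  st <- list(strategy = strategy, skill_up = skill_up,
             skill_down = skill_down, excitability = 1)
  class(st) <- "latent_state"
  st$excitability <- if (is.null(excitability)) {
    if (is.null(params)) 1 else expected_excitability(st, params)
  } else excitability
  stopifnot(st$excitability > 0)
  st
}

#' Expected excitability of a latent state
#'
#' `1 + skill_up * (up_asymptote - 1)` under UP,
#' `1 - skill_down * (1 - down_asymptote)` under DOWN, and exactly 1 at
#' REST.
#'
#' @param state a [latent_state()].
#' @param params a [participant_params()].
#' @return The deterministic expected excitability multiplier.
#' @export
expected_excitability <- function(state, params) {
  switch(state$strategy,
         UP = 1 + state$skill_up * (params$up_asymptote - 1),
         DOWN = 1 - state$skill_down * (1 - params$down_asymptote),
         REST = 1)
}

#' Advance the latent state by one operant-learning step
#'
#' Skill in the active direction grows by `learn_rate` (capped at 1) when a
#' trial was both rewarded and the reward was veridical (contingent on the
#' actual MEP); sham reward leaves skill untouched. The returned state
#' carries a fresh excitability draw: the strategy's expected value plus
#' zero-mean Gaussian trial jitter.
#'
#' @param state a [latent_state()].
#' @param params a [participant_params()].
#' @param rewarded,veridical logical flags for the completed trial.
#' @param jitter logical; add trial-to-trial excitability jitter (uses the
#'   current RNG stream).
#' @return The updated `latent_state`.
#' @export
step_excitability <- function(state, params, rewarded, veridical,
                              jitter = TRUE) {
  if (isTRUE(rewarded) && isTRUE(veridical)) {
    if (state$strategy == "UP") {
      state$skill_up <- min(1, state$skill_up + params$learn_rate)
    } else if (state$strategy == "DOWN") {
      state$skill_down <- min(1, state$skill_down + params$learn_rate)
    }
  }
  mu <- expected_excitability(state, params)
  state$excitability <- if (jitter) {
    max(0.05, mu + stats::rnorm(1, 0, params$excit_jitter_sd))
  } else mu
  state
}

## MEP generation ------------------------------------------------------------

## Mean of the recruitment sigmoid at a given intensity and excitability.
mep_mean <- function(intensity, excitability, params) {
  params$mep_max /
    (1 + exp(-params$slope_k * (intensity * excitability - params$i50)))
}

#' Draw TMS-evoked MEP amplitudes
#'
#' Amplitude mean follows a sigmoid recruitment curve in *effective*
#' intensity (`intensity * excitability`), multiplied by mean-1 log-normal
#' noise with coefficient of variation `mep_noise_cv`.
#'
#' @param state a [latent_state()].
#' @param intensity stimulation intensity (% maximal stimulator output);
#'   vectorized.
#' @param params a [participant_params()].
#' @param n number of draws per intensity value (default: one per
#'   intensity).
#' @return MEP peak-to-peak amplitudes in mV.
#' @export
generate_mep <- function(state, intensity, params, n = length(intensity)) {
  stopifnot(all(intensity >= 0))
  mu <- mep_mean(rep_len(intensity, n), state$excitability, params)
  mu * rlnorm_cv(n, params$mep_noise_cv)
}

## Background EMG ------------------------------------------------------------

#' Synthesize 4-channel background surface EMG
#'
#' Zero-mean Gaussian noise at 2000 Hz whose 100 ms rms sits at the
#' per-muscle resting level; a tension episode raises the noise level above
#' the 7 uV gate threshold on the selected channels.
#'
#' @param params a [participant_params()].
#' @param duration_ms trace duration in milliseconds.
#' @param tense logical; insert a tension episode.
#' @param tense_channels channels affected by the episode.
#' @param tense_window fraction of the trace (start, end) covered by the
#'   episode.
#' @param tense_rms rms level during the episode (uV).
#' @param fs sampling rate (Hz).
#' @return A numeric matrix, samples x 4 channels (uV).
#' @export
generate_background_emg <- function(params, duration_ms, tense = FALSE,
                                    tense_channels = 1,
                                    tense_window = c(0.25, 0.75),
                                    tense_rms = 15, fs = 2000) {
  n <- as.integer(round(duration_ms * fs / 1000))
  stopifnot(n >= 1)
  x <- matrix(stats::rnorm(n * 4), n, 4)
  x <- sweep(x, 2, params$emg_rest_rms, `*`)
  if (tense) {
    i0 <- max(1L, as.integer(ceiling(tense_window[1] * n)))
    i1 <- as.integer(floor(tense_window[2] * n))
    for (ch in tense_channels) {
      x[i0:i1, ch] <- stats::rnorm(i1 - i0 + 1L, 0, tense_rms)
    }
  }
  x
}

## Paired-pulse generation ----------------------------------------------------

## Conditioning-intensity -> conditioned/test ratio maps (rest state).
cs_ratio_map <- function(protocol, cs_intensity, params) {
  switch(protocol,
         SICI = 1 - params$sici_inh_max *
           stats::plogis((cs_intensity - params$sici_cs_mid) /
                           params$sici_cs_width),
         LICI = ,
         LCD = 1 - params$lici_inh_max *
           stats::plogis((cs_intensity - params$lici_cs_mid) /
                           params$lici_cs_width))
}

#' Draw a conditioned (paired-pulse) MEP amplitude
#'
#' SICI and LICI scale the single-pulse amplitude by a state-independent
#' conditioned/test ratio (from the conditioning-intensity map, or the
#' fixed `sici_ratio` / `lici_ratio` when the protocol carries no explicit
#' conditioning intensity). LCD returns the single-pulse amplitude times
#' `1 + gain`, where the gain is `lcd_gain_up/100 * skill_up` in the UP
#' state, `lcd_gain_down/100 * skill_down` in the DOWN state, and 0 at
#' rest.
#'
#' @param state a [latent_state()].
#' @param protocol a [pp_protocol()].
#' @param params a [participant_params()].
#' @param n number of draws.
#' @return Conditioned MEP amplitudes in mV.
#' @export
conditioned_mep <- function(state, protocol, params, n = 1) {
  stopifnot(inherits(protocol, "pp_protocol"))
  base_ratio <- switch(protocol$name,
    SICI = if (is.na(protocol$cs_intensity)) params$sici_ratio else
      cs_ratio_map("SICI", protocol$cs_intensity, params),
    LICI = if (is.na(protocol$cs_intensity)) params$lici_ratio else
      cs_ratio_map("LICI", protocol$cs_intensity, params),
    LCD = 1)
  gain <- if (protocol$name == "LCD") {
    switch(state$strategy,
           UP = params$lcd_gain_up / 100 * state$skill_up,
           DOWN = params$lcd_gain_down / 100 * state$skill_down,
           REST = 0)
  } else 0
  mu <- mep_mean(protocol$ts_intensity, state$excitability, params) *
    base_ratio * (1 + gain)
  mu * rlnorm_cv(n, params$mep_noise_cv)
}
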