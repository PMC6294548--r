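## trial_engine: the closed-loop experiment ----------------------------------
##
## Calibration protocols (resting motor threshold, recruitment curve,
## baseline), the EMG-gated trial state machine, feedback/reward logic,
## the adaptive criterion staircase, the fixed-rate sham schedule for the
## control group, and block/session scheduling for every block type.

#' Session configuration
#'
#' Protocol constants of one neurofeedback session. Defaults follow the
#' standard paradigm: 4 blocks of 30 feedback trials per day, a 20-trial
#' baseline, 12-trial post-rest measurements, a 7 uV / 100 ms / 500 ms
#' EMG gate, 5.5--8.5 s fixation, the >70 % / >90 % criterion staircase
#' with 10 % / 20 % steps, and a 66 % fixed-rate sham schedule for the
#' control group.
#'
#' @param condition training direction, `"UP"` or `"DOWN"`.
#' @param group `"experimental"` (veridical feedback) or `"control"`
#'   (sham).
#' @param trials_per_block,blocks_per_day,baseline_trials,post_trials
#'   block sizes.
#' @param gate_threshold uV rms gate limit per muscle.
#' @param gate_window rms window in ms.
#' @param gate_sustain required sub-threshold duration in ms.
#' @param fixation_range fixation interval bounds in seconds.
#' @param staircase_thresholds block success fractions that trigger a
#'   criterion step.
#' @param staircase_steps step fractions applied above each threshold.
#' @param sham_rate fixed reward rate of the control schedule.
#' @param seed RNG seed of the session.
#' @return An object of class `session_config`.
#' @export
session_config <- function(condition = c("UP", "DOWN"),
                           group = c("experimental", "control"),
                           trials_per_block = 30, blocks_per_day = 4,
                           baseline_trials = 20, post_trials = 12,
                           gate_threshold = 7, gate_window = 100,
                           gate_sustain = 500,
                           fixation_range = c(5.5, 8.5),
                           staircase_thresholds = c(0.70, 0.90),
                           staircase_steps = c(0.10, 0.20),
                           sham_rate = 0.66, seed = 1L) {
  condition <- match.arg(condition)
  group <- match.arg(group)
  stopifnot(sham_rate > 0, sham_rate < 1,
            fixation_range[1] <= fixation_range[2],
            diff(staircase_thresholds) > 0)
  structure(list(condition = condition, group = group,
                 trials_per_block = trials_per_block,
                 blocks_per_day = blocks_per_day,
                 baseline_trials = baseline_trials,
                 post_trials = post_trials,
                 gate_threshold = gate_threshold,
                 gate_window = gate_window, gate_sustain = gate_sustain,
                 fixation_range = fixation_range,
                 staircase_thresholds = staircase_thresholds,
                 staircase_steps = staircase_steps,
                 sham_rate = sham_rate, seed = as.integer(seed)),
            class = "session_config")
}

## Calibration ---------------------------------------------------------------

#' Estimate the resting motor threshold
#'
#' Ascends the intensity grid and returns the lowest intensity at which
#' at least 5 of 10 simulated pulses exceed 50 uV peak-to-peak.
#'
#' @param params a [participant_params()].
#' @param grid candidate intensities (% maximal output), sorted ascending.
#' @param n_pulses pulses per intensity.
#' @param min_hits required supra-threshold count.
#' @param threshold_mv MEP threshold in mV.
#' @return The RMT in % maximal stimulator output.
#' @export
estimate_rmt <- function(params, grid = seq(25, 70), n_pulses = 10,
                         min_hits = 5, threshold_mv = 0.05) {
  stopifnot(!is.unsorted(grid))
  rest <- latent_state("REST")
  for (int in grid) {
    meps <- generate_mep(rest, rep(int, n_pulses), params)
    if (sum(meps >= threshold_mv) >= min_hits) return(int)
  }
  stop("calibration failure: no grid intensity reached the RMT criterion")
}

#' Measure the recruitment curve and choose the test intensity
#'
#' Applies 6 pulses at 10 intensities relative to RMT (90--160, 180,
#' 190 %) in randomized order. The recorded maximal MEP is the largest
#' per-intensity mean; the test intensity is where the fitted sigmoid
#' reaches half of its plateau (the fitted half-max intensity), falling
#' back to monotone interpolation at half the recorded maximum when the
#' fit fails.
#'
#' @param params a [participant_params()].
#' @param rmt resting motor threshold (% maximal output).
#' @param n_per pulses per intensity.
#' @return A list of class `calibration_result` (without baseline):
#'   `rmt`, `recruitment` (data frame), `mep_max` (mV), `test_intensity`
#'   (% maximal output).
#' @export
measure_recruitment_curve <- function(params, rmt, n_per = 6) {
  rel <- c(0.9, 1, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.8, 1.9)
  ints <- rmt * rel
  order_ix <- sample(rep(seq_along(ints), each = n_per))
  rest <- latent_state("REST")
  amps <- generate_mep(rest, ints[order_ix], params)
  means <- vapply(seq_along(ints),
                  function(i) mean(amps[order_ix == i]), numeric(1))
  mep_max <- max(means)
  rec <- data.frame(pct_rmt = 100 * rel, intensity = ints,
                    mean_mv = means)
  ## fit on the log scale: amplitude noise is multiplicative, so log
  ## residuals are approximately homoscedastic across the curve
  fit <- tryCatch(
    minpack.lm::nlsLM(log(mean_mv) ~ log(M) +
                        stats::plogis(k * (intensity - i50), log.p = TRUE),
                      data = rec,
                      start = list(M = mep_max, k = 0.3,
                                   i50 = stats::median(ints)),
                      lower = c(M = 1e-3, k = 1e-3, i50 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    ## half of the fitted plateau is reached exactly at the fitted i50
    test_intensity <- cf[["i50"]]
    if (which.max(means) == length(means) &&
        means[length(means)] > 1.2 * means[length(means) - 2]) {
      warning("recruitment curve may not have plateaued; using observed maximum")
    }
  } else {
    mono <- cummax(means[order(ints)])
    test_intensity <- stats::approx(mono, sort(ints),
                                    xout = mep_max / 2, ties = "ordered",
                                    rule = 2)$y
    warning("sigmoid fit failed; interpolating the recruitment curve")
  }
  structure(list(rmt = rmt, recruitment = rec, mep_max = mep_max,
                 test_intensity = as.numeric(test_intensity)),
            class = "calibration_result")
}

#' Calibrate a participant for closed-loop testing
#'
#' RMT search, recruitment curve, and the 20-MEP resting baseline at the
#' chosen test intensity.
#'
#' @param params a [participant_params()].
#' @param baseline_trials baseline MEP count.
#' @return A `calibration_result` with `baseline_mean` (mV) added.
#' @export
calibrate_participant <- function(params, baseline_trials = 20) {
  rmt <- estimate_rmt(params)
  cal <- measure_recruitment_curve(params, rmt)
  rest <- latent_state("REST")
  cal$baseline_mean <- mean(generate_mep(
    rest, rep(cal$test_intensity, baseline_trials), params))
  cal
}

## EMG gate ------------------------------------------------------------------

#' Run the EMG relaxation gate on a raw stream
#'
#' The gate passes at the first instant at which the trailing 100 ms rms
#' of all four channels has been below the threshold continuously for
#' `gate_sustain` ms. For samples earlier than one full window the rms is
#' taken over the available samples.
#'
#' @param emg_stream numeric matrix, samples x 4 channels (uV) at 2000 Hz.
#' @param config a [session_config()].
#' @param fs sampling rate (Hz).
#' @return A list: `passed` (logical), `time_s` (pass time in seconds, NA
#'   if the stream ended first).
#' @export
run_gate <- function(emg_stream, config = session_config(), fs = 2000) {
  x <- as.matrix(emg_stream)
  n <- nrow(x)
  win <- round(config$gate_window / 1000 * fs)
  sus <- round(config$gate_sustain / 1000 * fs)
  ok <- rep(TRUE, n)
  for (ch in seq_len(ncol(x))) {
    cs <- cumsum(x[, ch]^2)
    lo <- pmax(seq_len(n) - win, 0)
    width <- seq_len(n) - lo
    r <- sqrt((cs - c(0, cs)[lo + 1]) / width)
    ok <- ok & (r < config$gate_threshold)
  }
  ## pass at the first index i >= sus with no supra-threshold sample in
  ## the trailing sustain window (i-sus, i]
  bad <- cumsum(!ok)
  idx <- seq_len(n)
  bad_lag <- c(rep(0, min(sus, n)), utils::head(bad, max(n - sus, 0)))
  pass <- which(idx >= sus & (bad - bad_lag) == 0)
  if (length(pass)) {
    list(passed = TRUE, time_s = pass[1] / fs)
  } else {
    list(passed = FALSE, time_s = NA_real_)
  }
}

#' Sample the fixation interval
#'
#' Uniform draw over the configured range (default 5.5--8.5 s).
#'
#' @param config a [session_config()].
#' @param n number of draws.
#' @return Fixation durations in seconds.
#' @export
sample_fixation <- function(config = session_config(), n = 1) {
  stats::runif(n, config$fixation_range[1], config$fixation_range[2])
}

## Feedback, staircase, sham -------------------------------------------------

#' Reward decision for one feedback trial
#'
#' UP: rewarded iff the MEP exceeds the criterion; DOWN: rewarded iff it
#' is below. Equality is never rewarded (strict inequality).
#'
#' @param mep_mv measured MEP amplitude (mV).
#' @param criterion_mv current criterion amplitude (mV).
#' @param condition `"UP"` or `"DOWN"`.
#' @return Logical reward flag (vectorized).
#' @export
decide_feedback <- function(mep_mv, criterion_mv, condition) {
  stopifnot(all(mep_mv > 0), all(criterion_mv > 0))
  if (condition == "UP") mep_mv > criterion_mv else mep_mv < criterion_mv
}

#' Staircase state
#'
#' @param criterion_mv initial criterion amplitude (mV), normally the
#'   session baseline mean.
#' @return An object of class `staircase_state` with the criterion, the
#'   block success history and the applied step factors.
#' @export
staircase_state <- function(criterion_mv) {
  stopifnot(criterion_mv > 0)
  structure(list(criterion_mv = criterion_mv,
                 block_success_history = numeric(0),
                 step_factors = numeric(0)),
            class = "staircase_state")
}

#' Update the criterion staircase after a block
#'
#' Success above the upper threshold (default 0.90) steps the criterion
#' by the large fraction (default 20 %), success above the lower
#' threshold (0.70) by the small fraction (10 %); otherwise the criterion
#' is unchanged. Steps raise the criterion in UP sessions and lower it in
#' DOWN sessions, multiplicatively on the current criterion.
#'
#' @param stair a [staircase_state()].
#' @param block_success success fraction of the completed block.
#' @param condition `"UP"` or `"DOWN"`.
#' @param config a [session_config()] providing thresholds and steps.
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(stair, block_success, condition,
                             config = session_config()) {
  stopifnot(block_success >= 0, block_success <= 1)
  th <- config$staircase_thresholds
  stp <- config$staircase_steps
  step <- if (block_success > th[2]) stp[2] else
    if (block_success > th[1]) stp[1] else 0
  factor <- if (condition == "UP") 1 + step else 1 - step
  stair$criterion_mv <- stair$criterion_mv * factor
  stair$block_success_history <- c(stair$block_success_history,
                                   block_success)
  stair$step_factors <- c(stair$step_factors, factor)
  stair
}

#' Fixed-rate sham reward schedule
#'
#' Deterministic repeating pattern achieving the configured rate within
#' rounding (66 % gives the cyclic reward-reward-no pattern: 20 rewards
#' in 30 trials), independent of any measurement.
#'
#' @param n_trials number of trials.
#' @param sham_rate reward fraction.
#' @return Logical reward sequence.
#' @export
sham_schedule <- function(n_trials, sham_rate = 0.66) {
  stopifnot(n_trials >= 1, sham_rate > 0, sham_rate < 1)
  i <- seq_len(n_trials)
  ceiling(i * sham_rate) > ceiling((i - 1) * sham_rate)
}

## Block execution -----------------------------------------------------------

## Draw the logged 110-10 ms pre-pulse rms for n trials x 4 muscles from
## the relaxed-noise law (rms of a 200-sample Gaussian window), truncated
## below the gate threshold -- the gate guarantees relaxation in the final
## pre-pulse window.
draw_pre_rms <- function(n, params, config) {
  win <- round(config$gate_window / 1000 * 2000)
  out <- matrix(0, n, 4)
  for (m in 1:4) {
    r <- params$emg_rest_rms[m] * sqrt(stats::rchisq(n, win) / win)
    over <- r >= config$gate_threshold
    while (any(over)) {
      r[over] <- params$emg_rest_rms[m] *
        sqrt(stats::rchisq(sum(over), win) / win)
      over <- r >= config$gate_threshold
    }
    out[, m] <- r
  }
  colnames(out) <- c("pre_rms_rfdi", "pre_rms_radm", "pre_rms_rop",
                     "pre_rms_lfdi")
  out
}

## Assemble one block's trial rows.
block_rows <- function(pid, group, day, block, type, condition, n,
                       hemisphere, fixation, pauses, pre, mep, criterion,
                       rewarded, excit, baseline_id) {
  data.frame(participant = pid, group = group, day = day, block = block,
             trial = seq_len(n), trial_type = type,
             condition = condition, hemisphere = hemisphere,
             fixation_s = fixation, gated_pause_count = pauses,
             pre, mep_mv = mep, criterion_mv = criterion,
             rewarded = rewarded, excitability = excit,
             baseline_id = baseline_id, stringsAsFactors = FALSE)
}

## Rest-type block (baseline / post): no feedback, strategy REST.
run_rest_block <- function(pp, config, cal, day, block, type, n,
                           baseline_id) {
  params <- pp$params
  pre <- draw_pre_rms(n, params, config)
  exc <- pmax(0.05, 1 + stats::rnorm(n, 0, params$excit_jitter_sd))
  mep <- mep_mean(cal$test_intensity, exc, params) *
    rlnorm_cv(n, params$mep_noise_cv)
  block_rows(pp$id, config$group, day, block, type, NA_character_, n,
             "trained", sample_fixation(config, n),
             stats::rbinom(n, 1, params$p_tense), pre, mep, NA_real_,
             NA, exc, baseline_id)
}

## One feedback block; sequential when learning can occur, vectorized for
## the sham/control path. Returns rows, updated skills, success rate.
run_feedback_block <- function(pp, config, cal, stair, day, block,
                               baseline_id, type = "feedback",
                               give_feedback = TRUE) {
  params <- pp$params
  n <- config$trials_per_block
  condition <- config$condition
  veridical <- config$group == "experimental" && give_feedback
  pre <- draw_pre_rms(n, params, config)
  fixation <- sample_fixation(config, n)
  pauses <- stats::rbinom(n, 1, params$p_tense)
  sham <- sham_schedule(n, config$sham_rate)
  skill_key <- if (condition == "UP") "skill_up" else "skill_down"
  mep <- numeric(n); exc <- numeric(n); rewarded <- logical(n)
  st <- latent_state(condition, pp$skill_up, pp$skill_down,
                     params = params)
  for (t in seq_len(n)) {
    e <- max(0.05, expected_excitability(st, params) +
               stats::rnorm(1, 0, params$excit_jitter_sd))
    st$excitability <- e
    m <- generate_mep(st, cal$test_intensity, params, n = 1)
    r <- if (config$group == "experimental") {
      decide_feedback(m, stair$criterion_mv, condition)
    } else sham[t]
    if (veridical && r) {
      st[[skill_key]] <- min(1, st[[skill_key]] + params$learn_rate)
    }
    mep[t] <- m; exc[t] <- e; rewarded[t] <- r
  }
  pp$skill_up <- st$skill_up
  pp$skill_down <- st$skill_down
  shown <- if (give_feedback) rewarded else rep(NA, n)
  rows <- block_rows(pp$id, config$group, day, block, type, condition, n,
                     "trained", fixation, pauses, pre, mep,
                     stair$criterion_mv, shown, exc, baseline_id)
  list(rows = rows, participant = pp,
       success = mean(rewarded), state = st)
}

#' Run one neurofeedback training session (one day)
#'
#' Baseline block (20 resting MEPs, which also initializes the criterion),
#' then four blocks of 30 feedback trials with 12-MEP post-rest
#' measurements, updating the criterion staircase between blocks.
#'
#' @param pp participant container from [make_participant()].
#' @param config a [session_config()] (carries condition and group).
#' @param cal a `calibration_result` from [calibrate_participant()].
#' @param day day label used in the trial log.
#' @return A list: `trials` (data frame), `participant` (updated
#'   skills), `staircase`.
#' @export
run_session <- function(pp, config, cal, day = "S1") {
  rows <- list()
  bs <- run_rest_block(pp, config, cal, day, "BS", "baseline_rest",
                       config$baseline_trials, "BS")
  rows[["BS"]] <- bs
  stair <- staircase_state(mean(bs$mep_mv))
  for (b in seq_len(config$blocks_per_day)) {
    fb <- run_feedback_block(pp, config, cal, stair, day,
                             paste0("FB", b), "BS")
    pp <- fb$participant
    rows[[paste0("FB", b)]] <- fb$rows
    stair <- update_staircase(stair, fb$success, config$condition, config)
    rows[[paste0("P", b)]] <- run_rest_block(pp, config, cal, day,
                                             paste0("P", b), "post_rest",
                                             config$post_trials, "BS")
  }
  list(trials = do.call(rbind, rows), participant = pp, staircase = stair)
}

#' Run the EEG-session day
#'
#' Two half-sessions (UP and DOWN, order configurable), each with its own
#' 20-MEP baseline followed by two feedback blocks with 12-MEP post
#' measurements. Optionally attaches a 1.5 s pre-pulse EEG epoch to every
#' feedback trial.
#'
#' @param pp participant container.
#' @param config a [session_config()]; its `condition` is overridden per
#'   half.
#' @param cal calibration result.
#' @param day day label.
#' @param order order of the two halves.
#' @param record_eeg logical; synthesize EEG epochs for feedback trials.
#' @param n_channels,hotspot_index EEG geometry.
#' @param subject_shift subject-specific band shift
#'   ([draw_subject_shift()]).
#' @return A list: `trials`, `participant`, `epochs` (an `eeg_epochs`
#'   object covering the feedback trials in log order, or `NULL`),
#'   `epoch_trials` (row indices into `trials`).
#' @export
run_eeg_session <- function(pp, config, cal, day = "E",
                            order = c("UP", "DOWN"), record_eeg = FALSE,
                            n_channels = 2, hotspot_index = 1,
                            subject_shift = NULL) {
  rows <- list()
  ep_chunks <- list()
  for (half in order) {
    cfg <- config
    cfg$condition <- half
    bs_id <- paste0("BS_", half)
    bs <- run_rest_block(pp, cfg, cal, day, bs_id, "baseline_rest",
                         cfg$baseline_trials, bs_id)
    rows[[bs_id]] <- bs
    stair <- staircase_state(mean(bs$mep_mv))
    for (b in 1:2) {
      fb <- run_feedback_block(pp, cfg, cal, stair, day,
                               paste0(half, b), bs_id)
      pp <- fb$participant
      rows[[paste0(half, b)]] <- fb$rows
      if (record_eeg) {
        ep_chunks[[paste0(half, b)]] <- generate_eeg_epoch(
          fb$state, pp$params, n_epochs = nrow(fb$rows),
          n_channels = n_channels, hotspot_index = hotspot_index,
          strategy = half, subject_shift = subject_shift)
      }
      stair <- update_staircase(stair, fb$success, half, cfg)
      rows[[paste0("P_", half, b)]] <- run_rest_block(
        pp, cfg, cal, day, paste0("P_", half, b), "post_rest",
        cfg$post_trials, bs_id)
    }
  }
  trials <- do.call(rbind, rows)
  epochs <- NULL
  if (record_eeg) {
    nch <- length(ep_chunks[[1]]$data)
    dat <- lapply(seq_len(nch), function(ch) {
      do.call(cbind, lapply(ep_chunks, function(e) e$data[[ch]]))
    })
    strat <- unlist(lapply(ep_chunks, `[[`, "strategy"), use.names = FALSE)
    epochs <- structure(list(data = dat, strategy = strat,
                             hotspot = hotspot_index, fs = EEG_FS),
                        class = "eeg_epochs")
  }
  idx <- which(trials$trial_type == "feedback")
  list(trials = trials, participant = pp, epochs = epochs,
       epoch_trials = idx)
}

#' Run a special follow-up block
#'
#' `"feedback_free"`: full trial timing with the display suppressed (no
#' reward shown, no learning). `"retention"`: a 20-trial feedback block
#' run on skills decayed to `retention_frac` of their trained level.
#' `"opposite_hemisphere"`: 40 trials, 20 trained / 20 opposite in random
#' order, feedback only on trained-hemisphere trials; opposite-hemisphere
#' excitability is `1 + coupling * (trained deviation)`.
#'
#' @param pp participant container.
#' @param config session config (condition = trained direction tested).
#' @param cal calibration result.
#' @param type block type.
#' @param day,block labels for the log.
#' @param criterion_mv criterion for feedback decisions (defaults to the
#'   calibration baseline mean).
#' @return A list: `trials`, `participant`.
#' @export
run_special_block <- function(pp, config, cal,
                              type = c("feedback_free", "retention",
                                       "opposite_hemisphere"),
                              day = "F1", block = type,
                              criterion_mv = NULL) {
  type <- match.arg(type)
  params <- pp$params
  criterion_mv <- criterion_mv %||% cal$baseline_mean
  if (type == "retention") {
    pp$skill_up <- pp$skill_up * params$retention_frac
    pp$skill_down <- pp$skill_down * params$retention_frac
    cfg <- config
    cfg$trials_per_block <- 20
    stair <- staircase_state(criterion_mv)
    fb <- run_feedback_block(pp, cfg, cal, stair, day, block, NA,
                             type = "retention")
    return(list(trials = fb$rows, participant = fb$participant))
  }
  if (type == "feedback_free") {
    cfg <- config
    stair <- staircase_state(criterion_mv)
    fb <- run_feedback_block(pp, cfg, cal, stair, day, block, NA,
                             type = "feedback_free",
                             give_feedback = FALSE)
    return(list(trials = fb$rows, participant = fb$participant))
  }
  ## opposite_hemisphere: 20 trained (with feedback) + 20 opposite
  n <- 40
  hemi <- sample(rep(c("trained", "opposite"), each = n / 2))
  pre <- draw_pre_rms(n, params, config)
  st <- latent_state(config$condition, pp$skill_up, pp$skill_down,
                     params = params)
  mep <- numeric(n); exc <- numeric(n); rewarded <- rep(NA, n)
  for (t in seq_len(n)) {
    e <- max(0.05, expected_excitability(st, params) +
               stats::rnorm(1, 0, params$excit_jitter_sd))
    e_eff <- if (hemi[t] == "trained") e else 1 + params$coupling * (e - 1)
    st$excitability <- e_eff
    mep[t] <- generate_mep(st, cal$test_intensity, params, n = 1)
    exc[t] <- e_eff
    if (hemi[t] == "trained") {
      r <- decide_feedback(mep[t], criterion_mv, config$condition)
      rewarded[t] <- r
      if (config$group == "experimental" && r) {
        key <- if (config$condition == "UP") "skill_up" else "skill_down"
        st[[key]] <- min(1, st[[key]] + params$learn_rate)
      }
    }
  }
  pp$skill_up <- st$skill_up
  pp$skill_down <- st$skill_down
  rows <- block_rows(pp$id, config$group, day, block,
                     "opposite_hemisphere", config$condition, n, hemi,
                     sample_fixation(config, n),
                     stats::rbinom(n, 1, params$p_tense), pre, mep,
                     criterion_mv, rewarded, exc, NA)
  list(trials = rows, participant = pp)
}
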