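## Cohort drivers and raw-trace synthesis ------------------------------------

#' Participant containers
#'
#' `make_participant` wraps generative parameters with the mutable
#' learning state the engine threads through a course of sessions;
#' `make_trained_participant` starts with both skills at ceiling (used by
#' follow-up and paired-pulse experiments on trained subjects).
#'
#' @param params a [participant_params()].
#' @param id participant identifier.
#' @return An object of class `nf_participant`.
#' @export
make_participant <- function(params, id = 1L) {
  structure(list(params = params, id = id, skill_up = 0, skill_down = 0),
            class = "nf_participant")
}

#' @rdname make_participant
#' @export
make_trained_participant <- function(params, id = 1L) {
  pp <- make_participant(params, id)
  pp$skill_up <- 1
  pp$skill_down <- 1
  pp
}

#' Simulate a full neurofeedback training course for a cohort
#'
#' For each participant: calibration (RMT, recruitment curve, baseline),
#' four training days (two UP, two DOWN, alternating), and the EEG-session
#' day with its two half-sessions (UP and DOWN, each against its own
#' baseline). All randomness derives from `seed` via per-participant
#' seeds; the same seed reproduces the cohort bit for bit.
#'
#' @param n_participants cohort size.
#' @param group `"experimental"` (veridical feedback) or `"control"`
#'   (fixed-rate sham).
#' @param seed master seed.
#' @param days training-day labels; the first letter (U/D) sets the
#'   condition.
#' @param eeg_day logical; append the EEG-session day.
#' @param record_eeg logical; synthesize pre-pulse EEG epochs on the EEG
#'   day and return per-epoch band-power features.
#' @param n_channels,hotspot_index EEG geometry (channel 2 stands for the
#'   homologous opposite-hemisphere electrode).
#' @param config_fn optional function `(condition, group, seed)` returning
#'   the [session_config()] to use.
#' @param individual_calibration logical; after calibration, solve each
#'   participant's asymptotes against their own realized operating point
#'   ([recalibrate_asymptotes()]) so the trained group effect is carried
#'   by every subject rather than only in procedure expectation.
#' @return A list of class `nf_cohort`: `trials` (all participants'
#'   logs), `calibrations`, `participants`, and `features` (per-epoch
#'   band powers of EEG-day feedback trials, or `NULL`).
#' @export
simulate_experiment <- function(n_participants = 15,
                                group = c("experimental", "control"),
                                seed = 1, days = c("U1", "D1", "U2", "D2"),
                                eeg_day = TRUE, record_eeg = FALSE,
                                n_channels = 1, hotspot_index = 1,
                                config_fn = NULL,
                                individual_calibration = TRUE) {
  group <- match.arg(group)
  seeds <- derive_seeds(seed, n_participants)
  all_trials <- vector("list", n_participants)
  cals <- vector("list", n_participants)
  pps <- vector("list", n_participants)
  feats <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(seeds[i])
    params <- participant_params(seed = seeds[i])
    pp <- make_participant(params, id = i)
    cal <- calibrate_participant(params)
    if (individual_calibration) {
      params <- recalibrate_asymptotes(params, cal)
      pp$params <- params
    }
    shift <- draw_subject_shift(params)
    rows <- list()
    for (d in days) {
      cond <- if (startsWith(d, "U")) "UP" else "DOWN"
      cfg <- if (is.null(config_fn)) {
        session_config(condition = cond, group = group, seed = seeds[i])
      } else config_fn(cond, group, seeds[i])
      ses <- run_session(pp, cfg, cal, day = d)
      pp <- ses$participant
      rows[[d]] <- ses$trials
    }
    if (eeg_day) {
      cfg <- if (is.null(config_fn)) {
        session_config(condition = "UP", group = group, seed = seeds[i])
      } else config_fn("UP", group, seeds[i])
      ses <- run_eeg_session(pp, cfg, cal, day = "E",
                             record_eeg = record_eeg,
                             n_channels = n_channels,
                             hotspot_index = hotspot_index,
                             subject_shift = shift)
      pp <- ses$participant
      rows[["E"]] <- ses$trials
      if (record_eeg) {
        f <- band_power_features(ses$epochs)
        f$subject <- i
        f$mep_mv <- ses$trials$mep_mv[ses$epoch_trials]
        feats[[i]] <- f
      }
    }
    all_trials[[i]] <- do.call(rbind, rows)
    cals[[i]] <- cal
    pps[[i]] <- pp
  }
  structure(list(trials = do.call(rbind, all_trials),
                 calibrations = cals, participants = pps,
                 features = if (record_eeg) do.call(rbind, feats) else NULL,
                 group = group, seed = seed),
            class = "nf_cohort")
}

#' Simulate an EEG feature cohort of trained subjects
#'
#' Draws balanced UP/DOWN pre-pulse epoch sets for `n_subjects` trained
#' synthetic subjects (skills at ceiling, per-subject band-shift
#' heterogeneity) and extracts the per-epoch band-power features, without
#' running the closed-loop engine. This is the direct route to the
#' feature matrices used by the state classifier.
#'
#' @param n_subjects number of subjects.
#' @param n_per_state epochs per state per subject.
#' @param seed master seed.
#' @param n_channels 1 (hotspot only) or 2 (+ opposite-hemisphere
#'   electrode).
#' @param band_d optional override of the per-band effect sizes.
#' @param attach_mep logical; attach MEP amplitudes drawn from the
#'   corresponding excitability state (for the trial-wise regression).
#' @return A feature data frame (one row per epoch) with `subject`,
#'   `condition`, hotspot features, and `opp_*` columns when
#'   `n_channels == 2`.
#' @export
simulate_eeg_cohort <- function(n_subjects = 14, n_per_state = 60,
                                seed = 1, n_channels = 1, band_d = NULL,
                                attach_mep = FALSE) {
  seeds <- derive_seeds(seed, n_subjects, salt = 2L)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(seeds[i])
    params <- if (is.null(band_d)) participant_params(seed = seeds[i])
      else participant_params(band_d = band_d, seed = seeds[i])
    shift <- draw_subject_shift(params)
    st <- latent_state("UP", skill_up = 1, skill_down = 1,
                       params = params)
    strat <- rep(c("UP", "DOWN"), each = n_per_state)
    ep <- generate_eeg_epoch(st, params, n_epochs = length(strat),
                             n_channels = n_channels, hotspot_index = 1,
                             strategy = strat, subject_shift = shift)
    f <- band_power_features(ep, channel = 1)
    if (n_channels >= 2) {
      fo <- band_power_features(ep, channel = 2)
      keep <- c(band_names(), "ratio", paste0("scaled_", band_names()))
      names(fo) <- ifelse(names(fo) %in% keep, paste0("opp_", names(fo)),
                          names(fo))
      f <- cbind(f, fo[, startsWith(names(fo), "opp_"), drop = FALSE])
    }
    f$subject <- i
    if (attach_mep) {
      exc <- ifelse(strat == "UP",
                    1 + st$skill_up * (params$up_asymptote - 1),
                    1 - st$skill_down * (1 - params$down_asymptote)) +
        stats::rnorm(length(strat), 0, params$excit_jitter_sd)
      mu <- mep_mean(params$i50, pmax(exc, 0.05), params)
      f$mep_mv <- mu * rlnorm_cv(length(strat), params$mep_noise_cv)
    }
    out[[i]] <- f
  }
  do.call(rbind, out)
}

#' Build the classifier feature matrix from a feature table
#'
#' Nine features per electrode: the eight 1/f-scaled relative band powers
#' plus the low-gamma:high-alpha ratio; optionally the same nine from the
#' opposite-hemisphere electrode (18 columns).
#'
#' @param features a feature data frame ([band_power_features()] /
#'   [simulate_eeg_cohort()]).
#' @param electrodes `"hotspot"` or `c("hotspot", "opposite")`.
#' @return A list: `x` (feature matrix), `y` (condition factor).
#' @export
state_feature_matrix <- function(features, electrodes = "hotspot") {
  cols <- c(paste0("scaled_", band_names()), "ratio")
  x <- as.matrix(features[, cols])
  colnames(x) <- c(band_names(), "ratio")
  if ("opposite" %in% electrodes) {
    ocols <- paste0("opp_", cols)
    stopifnot(all(ocols %in% names(features)))
    xo <- as.matrix(features[, ocols])
    colnames(xo) <- paste0("opp_", c(band_names(), "ratio"))
    x <- cbind(x, xo)
  }
  list(x = x, y = factor(features$condition, levels = c("DOWN", "UP")))
}

## Raw-trace synthesis -------------------------------------------------------

#' Synthesize a raw single-trial EMG trace around a TMS pulse
#'
#' Background noise at the resting level, a saturating stimulus artifact
#' at pulse time, and a Gaussian-windowed ~130 Hz biphasic MEP waveform at
#' 22 ms latency whose peak-to-peak amplitude equals `amplitude_mv`. Used
#' by the trace-mode integration path and for exporting example raw data;
#' the offline pipeline ([background_rms()], [peak_to_peak()]) measures
#' this trace.
#'
#' @param amplitude_mv target MEP peak-to-peak amplitude (mV).
#' @param params a [participant_params()].
#' @param pre_ms,post_ms trace extent around the pulse (ms).
#' @param fs sampling rate (Hz).
#' @param muscle muscle index for the background level.
#' @return A list: `samples` (uV), `pulse_index`, `fs`.
#' @export
synth_mep_trace <- function(amplitude_mv, params, pre_ms = 150,
                            post_ms = 100, fs = 2000, muscle = 1) {
  n_pre <- round(pre_ms / 1000 * fs)
  n_post <- round(post_ms / 1000 * fs)
  n <- n_pre + n_post + 1L
  x <- stats::rnorm(n, 0, params$emg_rest_rms[muscle])
  pulse <- n_pre + 1L
  tau <- (seq_len(n) - pulse) / fs                 # seconds after pulse
  wave <- exp(-((tau - 0.025) / 0.004)^2) * sin(2 * pi * 130 *
                                                  (tau - 0.025))
  wave <- wave / (max(wave) - min(wave))
  x <- x + wave * amplitude_mv * 1000
  x[pulse + (0:2)] <- c(4000, -4000, 2000)         # stimulus artifact
  list(samples = x, pulse_index = pulse, fs = fs)
}

#' Export a simulated cohort to plain-text files
#'
#' Writes `trials.csv` (one row per trial), `features.csv` (per-epoch
#' band powers, if present) and `calibration.csv` (per participant) under
#' `dir`.
#'
#' @param cohort an `nf_cohort` from [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "trials.csv")
  utils::write.csv(cohort$trials, paths[1], row.names = FALSE)
  cal <- do.call(rbind, lapply(seq_along(cohort$calibrations), function(i) {
    cl <- cohort$calibrations[[i]]
    data.frame(participant = i, rmt = cl$rmt, mep_max = cl$mep_max,
               test_intensity = cl$test_intensity,
               baseline_mean = cl$baseline_mean)
  }))
  p2 <- file.path(dir, "calibration.csv")
  utils::write.csv(cal, p2, row.names = FALSE)
  paths <- c(paths, p2)
  if (!is.null(cohort$features)) {
    p3 <- file.path(dir, "features.csv")
    utils::write.csv(cohort$features, p3, row.names = FALSE)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
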