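## mep_pipeline: offline EMG/MEP processing ----------------------------------
##
## Filtering, background-EMG quantification, the exclusion cascade, block
## trimming, baseline normalization and effect summaries. All amplitude
## bookkeeping follows the convention: EMG in uV internally, MEP amplitudes
## reported in mV.

#' Zero-phase band-pass filter for EMG segments
#'
#' 4th-order Butterworth, applied forward and backward
#' ([signal::filtfilt]), 30--800 Hz by default at 2000 Hz sampling. The
#' pre-pulse segment and the MEP segment of a trial are filtered
#' independently of each other so that the MEP cannot smear into the
#' background-EMG estimate.
#'
#' @param x numeric vector, one EMG segment (uV).
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order Butterworth order.
#' @return The filtered segment.
#' @export
emg_bandpass <- function(x, low = 30, high = 800, fs = 2000, order = 4) {
  stopifnot(fs > 2 * high)
  if (length(x) < 3 * (order + 1)) {
    stop("segment too short for stable zero-phase filtering")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Background EMG rms in the 110 to 10 ms pre-pulse window
#'
#' Root mean square of the (filtered) samples in
#' `[pulse - 110 ms, pulse - 10 ms)` -- 200 samples at 2000 Hz.
#'
#' @param trace numeric vector of EMG samples (uV).
#' @param pulse_index sample index of TMS onset.
#' @param fs sampling rate in Hz.
#' @param filter logical; band-pass the window before computing rms.
#' @return rms in uV.
#' @export
background_rms <- function(trace, pulse_index, fs = 2000, filter = TRUE) {
  i0 <- pulse_index - round(0.110 * fs)
  i1 <- pulse_index - round(0.010 * fs) - 1L
  if (i0 < 1 || i1 > length(trace)) {
    stop("trace does not cover the 110-10 ms pre-pulse window")
  }
  seg <- trace[i0:i1]
  if (filter) seg <- emg_bandpass(seg, fs = fs)
  rms(seg)
}

#' Peak-to-peak MEP amplitude
#'
#' `max - min` of the (filtered) samples in the MEP search window,
#' reported in mV. The default window of 20--45 ms after the pulse covers
#' the conventional hand-muscle MEP latency and excludes the stimulus
#' artifact at pulse time.
#'
#' @param trace numeric vector of EMG samples (uV).
#' @param pulse_index sample index of TMS onset.
#' @param window post-pulse search window in ms, `c(from, to)`.
#' @param fs sampling rate in Hz.
#' @param filter logical; band-pass the window before measuring.
#' @return Peak-to-peak amplitude in mV.
#' @export
peak_to_peak <- function(trace, pulse_index, window = c(20, 45), fs = 2000,
                         filter = TRUE) {
  i0 <- pulse_index + round(window[1] / 1000 * fs)
  i1 <- pulse_index + round(window[2] / 1000 * fs)
  if (i0 < 1 || i1 > length(trace) || i1 <= i0) {
    stop("MEP window empty or outside the trace")
  }
  seg <- trace[i0:i1]
  if (filter) seg <- emg_bandpass(seg, fs = fs)
  (max(seg) - min(seg)) / 1000
}

#' Remove the extreme MEPs of one block
#'
#' Drops exactly one maximum and one minimum amplitude per block (first
#' occurrence on ties). Blocks with fewer than 3 trials are returned
#' untouched with a warning.
#'
#' @param amplitudes numeric vector of MEP amplitudes in one block.
#' @return Logical vector, `TRUE` for retained trials.
#' @export
trim_block_extremes <- function(amplitudes) {
  keep <- rep(TRUE, length(amplitudes))
  if (length(amplitudes) < 3) {
    warning("block has fewer than 3 trials; trimming skipped")
    return(keep)
  }
  keep[which.max(amplitudes)] <- FALSE
  keep[which(keep)[which.min(amplitudes[keep])]] <- FALSE
  keep
}

#' Apply the background-EMG and amplitude exclusion cascade
#'
#' Per-subject rules, in order, after block trimming:
#' (1) absolute background rms above 0.01 mV (10 uV) in the target muscle;
#' (2) background rms above the subject's mean + 2.5 SD over all trials;
#' (3) amplitude above `Q3 + 1.5 * (Q3 - Q1)` over the subject's whole
#' trial set (quartiles by linear interpolation of order statistics).
#' Each excluded trial carries the first failing rule as its reason.
#' Rules (2) and (3) use the trial pool remaining after trimming.
#'
#' @param bg_rms numeric vector of per-trial background rms (uV).
#' @param amplitude numeric vector of per-trial MEP amplitudes (mV).
#' @param block factor/vector identifying the block of each trial (for
#'   trimming); `NULL` skips trimming.
#' @param bg_abs_limit absolute background limit in uV.
#' @param bg_sd_mult SD multiplier of rule (2).
#' @param iqr_mult IQR multiplier of rule (3).
#' @param trim logical; apply block trimming first.
#' @return A data frame of class `cleaned_trials` with columns `retained`
#'   and `reason` (`"trimmed"`, `"bg_abs"`, `"bg_sd"`, `"amp_iqr"`,
#'   `"none"`).
#' @export
apply_exclusions <- function(bg_rms, amplitude, block = NULL,
                             bg_abs_limit = 10, bg_sd_mult = 2.5,
                             iqr_mult = 1.5, trim = TRUE) {
  n <- length(amplitude)
  stopifnot(length(bg_rms) == n)
  reason <- rep("none", n)
  if (trim && !is.null(block)) {
    for (b in unique(block)) {
      idx <- which(block == b)
      if (length(idx) >= 3) {
        reason[idx[!trim_block_extremes(amplitude[idx])]] <- "trimmed"
      }
    }
  }
  pool <- reason == "none"
  hit <- pool & bg_rms > bg_abs_limit
  reason[hit] <- "bg_abs"
  pool <- reason == "none"
  bg_lim <- mean(bg_rms[pool]) + bg_sd_mult * stats::sd(bg_rms[pool])
  hit <- pool & bg_rms > bg_lim
  reason[hit] <- "bg_sd"
  pool <- reason == "none"
  if (sum(pool) >= 4) {
    q <- stats::quantile(amplitude[pool], c(0.25, 0.75), type = 7,
                         names = FALSE)
    amp_lim <- q[2] + iqr_mult * (q[2] - q[1])
    hit <- pool & amplitude > amp_lim
    reason[hit] <- "amp_iqr"
  } else {
    warning("fewer than 4 trials in pool; quartile rule skipped")
  }
  out <- data.frame(retained = reason == "none", reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("cleaned_trials", class(out))
  out
}

#' Clean a simulated trial log
#'
#' Runs [apply_exclusions()] per participant on the MEP-bearing trials of
#' a trial log (feedback, baseline and post-rest trials on the trained
#' hemisphere), trimming within each (day, block) and pooling rules
#' (2)-(3) over the participant's whole set.
#'
#' @param trials a trial-log data frame from the engine (see
#'   [run_session()]).
#' @return `trials` with columns `retained` and `reason` added.
#' @export
clean_trials <- function(trials) {
  trials$retained <- NA
  trials$reason <- NA_character_
  mepish <- trials$trial_type %in%
    c("feedback", "baseline_rest", "post_rest", "feedback_free",
      "retention") &
    (is.na(trials$hemisphere) | trials$hemisphere == "trained")
  for (pid in unique(trials$participant)) {
    idx <- which(mepish & trials$participant == pid)
    if (!length(idx)) next
    blk <- interaction(trials$day[idx], trials$block[idx], drop = TRUE)
    cl <- apply_exclusions(trials$pre_rms_rfdi[idx], trials$mep_mv[idx],
                           block = blk)
    trials$retained[idx] <- cl$retained
    trials$reason[idx] <- cl$reason
  }
  trials
}

#' Percent change of a block mean from baseline
#'
#' @param block_mean,baseline_mean mean MEP amplitudes in mV.
#' @return `100 * (block_mean - baseline_mean) / baseline_mean`.
#' @export
percent_change_from_baseline <- function(block_mean, baseline_mean) {
  if (any(baseline_mean <= 0)) stop("baseline mean must be positive")
  100 * (block_mean - baseline_mean) / baseline_mean
}

#' UP minus DOWN modulation
#'
#' Difference of the normalized percent changes; larger values mean a
#' stronger dissociation of the two trained states.
#'
#' @param up_pct,down_pct percent changes from baseline.
#' @return `up_pct - down_pct`.
#' @export
up_down_modulation <- function(up_pct, down_pct) up_pct - down_pct

#' Cohen's d (paired and two-group forms)
#'
#' `paired`: mean of the differences over the SD of the differences
#' (`x` are differences, or `x`, `y` paired samples). `pooled`: mean
#' difference over the pooled SD of two independent groups.
#'
#' @param x numeric vector (differences, or group 1).
#' @param y optional second sample.
#' @param type `"paired"` or `"pooled"`.
#' @return The standardized effect size.
#' @export
cohens_d <- function(x, y = NULL, type = c("paired", "pooled")) {
  type <- match.arg(type)
  if (type == "paired") {
    d <- if (is.null(y)) x else x - y
    if (length(d) < 2) stop("need at least 2 observations")
    s <- stats::sd(d)
    if (s == 0) stop("zero variance; effect size undefined")
    mean(d) / s
  } else {
    stopifnot(!is.null(y))
    if (length(x) < 2 || length(y) < 2) stop("need at least 2 per group")
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
    if (sp == 0) stop("zero variance; effect size undefined")
    (mean(x) - mean(y)) / sp
  }
}

#' Per-block summary of a cleaned trial log
#'
#' Means of retained MEPs per (participant, day, block) plus the percent
#' change from the block's session baseline (the `baseline_id` column of
#' the log links every block to its same-day baseline block).
#'
#' @param trials a cleaned trial log (see [clean_trials()]).
#' @return A data frame with one row per MEP block: `participant`, `day`,
#'   `block`, `condition`, `trial_type`, `n`, `mean_mv`, `pct_change`.
#' @export
summarize_blocks <- function(trials) {
  if (is.null(trials$retained)) trials <- clean_trials(trials)
  keep <- !is.na(trials$retained) & trials$retained
  tr <- trials[keep, , drop = FALSE]
  key <- interaction(tr$participant, tr$day, tr$block, drop = TRUE)
  agg <- do.call(rbind, lapply(split(tr, key), function(g) {
    data.frame(participant = g$participant[1], day = g$day[1],
               block = g$block[1], condition = g$condition[1],
               trial_type = g$trial_type[1],
               baseline_id = g$baseline_id[1],
               n = nrow(g), mean_mv = mean(g$mep_mv),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  base <- agg[agg$trial_type == "baseline_rest", ]
  bmap <- stats::setNames(base$mean_mv,
                          paste(base$participant, base$day, base$block))
  ref <- bmap[paste(agg$participant, agg$day, agg$baseline_id)]
  agg$pct_change <- NA_real_
  ok <- !is.na(ref)
  agg$pct_change[ok] <- percent_change_from_baseline(agg$mean_mv[ok],
                                                     ref[ok])
  agg
}
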