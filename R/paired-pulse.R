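## paired_pulse: SICI / LICI / LCD protocol logic ----------------------------

#' Paired-pulse protocol definition
#'
#' Enforces the protocol invariants at construction: SICI uses a 1.97 ms
#' inter-stimulus interval with a sub-threshold conditioning stimulus,
#' LICI a 100 ms interval, and LCD a 220 ms interval with LICI's
#' conditioning intensity. The test stimulus is the neurofeedback test
#' intensity.
#'
#' @param name `"SICI"`, `"LICI"` or `"LCD"`.
#' @param ts_intensity test-stimulus intensity (% maximal output).
#' @param cs_intensity conditioning-stimulus intensity (% RMT); `NA`
#'   falls back to the participant's fixed rest ratios.
#' @param isi_ms inter-stimulus interval; must match the protocol.
#' @return An object of class `pp_protocol`.
#' @export
pp_protocol <- function(name = c("SICI", "LICI", "LCD"), ts_intensity,
                        cs_intensity = NA_real_, isi_ms = NULL) {
  name <- match.arg(name)
  expected_isi <- c(SICI = 1.97, LICI = 100, LCD = 220)[[name]]
  isi_ms <- isi_ms %||% expected_isi
  if (!isTRUE(all.equal(isi_ms, expected_isi))) {
    stop(sprintf("protocol error: %s requires an ISI of %g ms", name,
                 expected_isi))
  }
  if (name == "SICI" && !is.na(cs_intensity) && cs_intensity >= 100) {
    stop("protocol error: SICI conditioning stimulus must be sub-threshold")
  }
  structure(list(name = name, ts_intensity = ts_intensity,
                 cs_intensity = cs_intensity, isi_ms = isi_ms),
            class = "pp_protocol")
}

#' Personalized conditioning-stimulus search
#'
#' Evaluates candidate conditioning intensities over the protocol's grid
#' (SICI: 50--90 % RMT in 5 % steps; LICI: 106--114 % RMT in 2 % steps),
#' measuring the mean conditioned-to-single-pulse ratio per candidate,
#' and returns the candidate closest to 50 % inhibition (ties: the lowest
#' intensity). LCD inherits the LICI result.
#'
#' @param params a [participant_params()].
#' @param protocol_name `"SICI"` or `"LICI"`.
#' @param cal a `calibration_result` (provides the test intensity).
#' @param grid candidate intensities (% RMT); protocol default if `NULL`.
#' @param n_per trials per candidate.
#' @return The chosen conditioning intensity (% RMT), with attribute
#'   `"ratios"` (measured ratio per candidate).
#' @export
search_conditioning_intensity <- function(params, protocol_name, cal,
                                          grid = NULL, n_per = 10) {
  protocol_name <- match.arg(protocol_name, c("SICI", "LICI"))
  grid <- grid %||% if (protocol_name == "SICI") seq(50, 90, by = 5) else
    seq(106, 114, by = 2)
  rest <- latent_state("REST")
  ratios <- vapply(grid, function(cs) {
    proto <- pp_protocol(protocol_name, cal$test_intensity, cs)
    cond <- conditioned_mep(rest, proto, params, n = n_per)
    sp <- generate_mep(rest, rep(cal$test_intensity, n_per), params)
    100 * mean(cond) / mean(sp)
  }, numeric(1))
  if (all(ratios >= 100)) {
    warning("no candidate achieved inhibition; returning nearest candidate")
  }
  best <- grid[which.min(abs(ratios - 50))]
  attr(best, "ratios") <- stats::setNames(ratios, grid)
  best
}

#' Build an interleaved paired-pulse block sequence
#'
#' Exactly a quarter each of single-pulse, SICI, LICI and LCD trials in a
#' seeded random order; feedback is attached only to single-pulse trials.
#'
#' @param n_trials block length (divisible by 4).
#' @param seed optional RNG seed for the permutation.
#' @return Character vector of trial types (`"SP"`, `"SICI"`, `"LICI"`,
#'   `"LCD"`).
#' @export
build_interleaved_block <- function(n_trials = 24, seed = NULL) {
  if (n_trials %% 4 != 0) stop("n_trials must be divisible by 4")
  if (!is.null(seed)) set.seed(seed)
  sample(rep(c("SP", "SICI", "LICI", "LCD"), each = n_trials / 4))
}

#' Conditioned-to-single-pulse ratio
#'
#' @param conditioned conditioned MEP amplitudes (mV).
#' @param sp single-pulse MEP amplitudes from the same block (mV).
#' @return `100 * mean(conditioned) / mean(sp)` (% of SP).
#' @export
pp_ratio <- function(conditioned, sp) {
  stopifnot(length(conditioned) >= 1, length(sp) >= 1)
  if (mean(sp) <= 0) stop("zero single-pulse mean")
  100 * mean(conditioned) / mean(sp)
}

## Run one paired-pulse measurement block in a given state. protocols is a
## named list of pp_protocol objects (SICI, LICI, LCD).
run_pp_block <- function(pp, config, cal, protocols, state_label, day,
                         block, n_trials = 24, criterion_mv = NULL) {
  params <- pp$params
  criterion_mv <- criterion_mv %||% cal$baseline_mean
  types <- if (state_label == "REST") {
    sample(rep(c("SP", "SICI", "LICI", "LCD"), each = n_trials / 4))
  } else {
    build_interleaved_block(n_trials)
  }
  st <- latent_state(if (state_label == "REST") "REST" else state_label,
                     pp$skill_up, pp$skill_down, params = params)
  n <- length(types)
  pre <- draw_pre_rms(n, params, config)
  mep <- numeric(n); exc <- numeric(n); rewarded <- rep(NA, n)
  for (t in seq_len(n)) {
    st$excitability <- max(0.05, expected_excitability(st, params) +
                             stats::rnorm(1, 0, params$excit_jitter_sd))
    exc[t] <- st$excitability
    if (types[t] == "SP") {
      mep[t] <- generate_mep(st, cal$test_intensity, params, n = 1)
      if (state_label != "REST") {
        rewarded[t] <- decide_feedback(mep[t], criterion_mv,
                                       state_label)
      }
    } else {
      mep[t] <- conditioned_mep(st, protocols[[types[t]]], params)
    }
  }
  block_rows(pp$id, config$group, day, block,
             paste0("pp_", types), state_label, n, "trained",
             sample_fixation(config, n),
             stats::rbinom(n, 1, params$p_tense), pre, mep,
             criterion_mv, rewarded, exc, NA)
}

#' Run the paired-pulse experiment for one trained participant
#'
#' For each tested state (UP, DOWN; separate days): a resting baseline
#' paired-pulse block (20 trials of each protocol plus 20 single pulses)
#' immediately before three 24-trial interleaved neurofeedback blocks in
#' that state. Conditioning intensities come from the personalized search
#' (LCD inherits LICI's).
#'
#' @param pp participant container (normally trained; see
#'   [make_trained_participant()]).
#' @param config a [session_config()].
#' @param cal calibration result.
#' @param states states tested on separate days.
#' @param n_blocks interleaved blocks per state.
#' @return A list: `trials` (log), `summary` (per protocol and context
#'   the conditioned/SP ratio, % of SP), `cs` (chosen conditioning
#'   intensities).
#' @export
run_pp_participant <- function(pp, config, cal, states = c("UP", "DOWN"),
                               n_blocks = 3) {
  params <- pp$params
  cs_sici <- search_conditioning_intensity(params, "SICI", cal)
  cs_lici <- search_conditioning_intensity(params, "LICI", cal)
  protocols <- list(
    SICI = pp_protocol("SICI", cal$test_intensity, as.numeric(cs_sici)),
    LICI = pp_protocol("LICI", cal$test_intensity, as.numeric(cs_lici)),
    LCD = pp_protocol("LCD", cal$test_intensity, as.numeric(cs_lici)))
  rows <- list()
  for (stt in states) {
    day <- paste0("PP_", stt)
    rows[[paste0(day, "_base")]] <- run_pp_block(
      pp, config, cal, protocols, "REST", day, "BASE", n_trials = 80)
    for (b in seq_len(n_blocks)) {
      rows[[paste0(day, "_B", b)]] <- run_pp_block(
        pp, config, cal, protocols, stt, day, paste0("B", b))
    }
  }
  trials <- do.call(rbind, rows)
  summ <- pp_summarize(trials)
  list(trials = trials, summary = summ,
       cs = c(SICI = as.numeric(cs_sici), LICI = as.numeric(cs_lici)))
}

#' Summarize paired-pulse ratios per protocol and context
#'
#' Computes the conditioned/SP percentage per protocol within each
#' (day, state) context of a paired-pulse trial log, using the same
#' context's single-pulse trials as the denominator.
#'
#' @param trials a paired-pulse trial log from [run_pp_participant()].
#' @return Data frame: `participant`, `day`, `context` (`"baseline"` or
#'   the state), `protocol`, `ratio_pct`, `n`.
#' @export
pp_summarize <- function(trials) {
  pp_t <- trials[startsWith(trials$trial_type, "pp_"), , drop = FALSE]
  out <- list()
  for (key in unique(paste(pp_t$participant, pp_t$day, pp_t$condition))) {
    g <- pp_t[paste(pp_t$participant, pp_t$day, pp_t$condition) == key, ]
    sp <- g$mep_mv[g$trial_type == "pp_SP"]
    for (proto in c("SICI", "LICI", "LCD")) {
      cond <- g$mep_mv[g$trial_type == paste0("pp_", proto)]
      if (!length(cond) || !length(sp)) next
      out[[paste(key, proto)]] <- data.frame(
        participant = g$participant[1], day = g$day[1],
        context = if (g$condition[1] == "REST") "baseline" else
          g$condition[1],
        protocol = proto, ratio_pct = pp_ratio(cond, sp),
        n = length(cond), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' State-dependence contrast of the paired-pulse ratios
#'
#' Per protocol, the time-by-state interaction
#' `(UP - baseline_UP) - (DOWN - baseline_DOWN)` of the conditioned/SP
#' ratios, tested with a seeded subject-level sign-flip permutation of
#' the state labels and FDR-corrected across the three protocols.
#'
#' @param summary a cohort summary (rows from [pp_summarize()], several
#'   participants).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return Data frame of class `pp_contrast`: per protocol the mean
#'   UP-baseline and DOWN-baseline differences, the interaction, `p`,
#'   `p_fdr`.
#' @export
state_modulation_contrast <- function(summary, n_perm = 2000, seed = 1) {
  protos <- c("SICI", "LICI", "LCD")
  per_subj <- function(proto) {
    sub <- summary[summary$protocol == proto, ]
    ids <- unique(sub$participant)
    t(vapply(ids, function(id) {
      g <- sub[sub$participant == id, ]
      up <- g$ratio_pct[g$context == "UP" & g$day == "PP_UP"]
      bup <- g$ratio_pct[g$context == "baseline" & g$day == "PP_UP"]
      dn <- g$ratio_pct[g$context == "DOWN" & g$day == "PP_DOWN"]
      bdn <- g$ratio_pct[g$context == "baseline" & g$day == "PP_DOWN"]
      if (!length(bup) || !length(bdn)) {
        stop("missing baseline paired-pulse block")
      }
      c(dup = mean(up) - mean(bup), ddn = mean(dn) - mean(bdn))
    }, numeric(2)))
  }
  set.seed(seed)
  res <- lapply(protos, function(proto) {
    d <- per_subj(proto)
    inter <- d[, "dup"] - d[, "ddn"]
    obs <- mean(inter)
    null <- vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), length(inter), replace = TRUE)
      mean(inter * flips)
    }, numeric(1))
    p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    data.frame(protocol = proto, mean_diff_up = mean(d[, "dup"]),
               mean_diff_down = mean(d[, "ddn"]), interaction = obs,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("pp_contrast", class(out))
  out
}
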