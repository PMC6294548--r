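test_that("RMT search implements the 5-of-10 rule on an ascending grid", {
  p <- exact_params                       # noise-free: deterministic MEPs
  ## the mean MEP crosses the (slightly lowered, to avoid a knife-edge
  ## float comparison) threshold exactly at the true RMT by construction
  expect_equal(estimate_rmt(p, grid = 30:60, threshold_mv = 0.049), p$rmt)
  expect_error(estimate_rmt(p, grid = 30:35), "calibration failure")
  ## Monte-Carlo: median estimated RMT within one grid step of the
  ## intensity where P(MEP >= 50 uV) = 0.5 (brute-force oracle)
  pn <- default_params
  sdlog <- sqrt(log(1 + pn$mep_noise_cv^2))
  p_hit <- function(i) {
    mu <- pn$mep_max / (1 + exp(-pn$slope_k * (i - pn$i50)))
    stats::plnorm(0.05 / mu, -sdlog^2 / 2, sdlog, lower.tail = FALSE)
  }
  oracle <- stats::uniroot(function(i) p_hit(i) - 0.5, c(30, 60))$root
  set.seed(5)
  est <- replicate(300, estimate_rmt(pn, grid = 30:60))
  expect_lte(abs(stats::median(est) - oracle), 1)
})

test_that("recruitment curve uses 10 intensities x 6 pulses and finds half-max", {
  p <- exact_params
  set.seed(2)
  cal <- measure_recruitment_curve(p, rmt = p$rmt)
  expect_equal(nrow(cal$recruitment), 10L)
  expect_equal(cal$recruitment$pct_rmt,
               c(90, 100, 110, 120, 130, 140, 150, 160, 180, 190))
  ## noiseless means equal the true curve at each intensity
  expect_equal(cal$recruitment$mean_mv,
               p$mep_max * stats::plogis(p$slope_k *
                                           (cal$recruitment$intensity -
                                              p$i50)),
               tolerance = 1e-8)
  ## half of the plateau is evoked at the chosen test intensity
  pred <- p$mep_max * stats::plogis(p$slope_k * (cal$test_intensity -
                                                   p$i50))
  expect_equal(pred, p$mep_max / 2, tolerance = 0.01)
})

test_that("default calibration lands near 130 % RMT on average", {
  set.seed(31)
  ratio <- replicate(25, {
    p <- default_params
    rmt <- estimate_rmt(p)
    cal <- quiet(measure_recruitment_curve(p, rmt))
    cal$test_intensity / rmt
  })
  expect_equal(mean(ratio), 1.30, tolerance = 0.04)
})

test_that("the EMG gate enforces threshold, sustain and re-arming", {
  cfg <- session_config()
  relaxed <- matrix(4, nrow = 4000, ncol = 4)       # constant 4 uV rms
  g <- run_gate(relaxed, cfg)
  expect_true(g$passed)
  expect_equal(g$time_s, 0.5)                       # passes at gate_sustain
  tense <- relaxed; tense[, 2] <- 7.5
  expect_false(run_gate(tense, cfg)$passed)
  ## channel drops below threshold at t0 = 1 s: pass >= t0 + 500 ms
  drop <- matrix(4, nrow = 6000, ncol = 4)
  drop[1:2000, 3] <- 7.5
  g3 <- run_gate(drop, cfg)
  expect_true(g3$passed)
  expect_gte(g3$time_s, 1.5)
  expect_lte(g3$time_s, 1.6)
})

test_that("fixation sampling is uniform on the configured interval", {
  cfg <- session_config()
  set.seed(4)
  x <- sample_fixation(cfg, 1e5)
  expect_gte(min(x), 5.5)
  expect_lte(max(x), 8.5)
  expect_equal(mean(x), 7.0, tolerance = 0.01)
  cfg$fixation_range <- c(6, 6)
  expect_equal(sample_fixation(cfg, 10), rep(6, 10))
})

test_that("reward rule is direction-dependent and strict at equality", {
  expect_true(decide_feedback(1.2, 1.0, "UP"))
  expect_false(decide_feedback(1.2, 1.0, "DOWN"))
  expect_true(decide_feedback(0.8, 1.0, "DOWN"))
  expect_false(decide_feedback(1.0, 1.0, "UP"))
  expect_false(decide_feedback(1.0, 1.0, "DOWN"))
})

test_that("staircase steps 10 % above 70 % and 20 % above 90 %, signed by direction", {
  cfg <- session_config()
  st <- staircase_state(1.0)
  expect_equal(update_staircase(st, 22 / 30, "UP", cfg)$criterion_mv, 1.10)
  expect_equal(update_staircase(st, 28 / 30, "UP", cfg)$criterion_mv, 1.20)
  expect_equal(update_staircase(st, 0.60, "UP", cfg)$criterion_mv, 1.0)
  expect_equal(update_staircase(st, 22 / 30, "DOWN", cfg)$criterion_mv,
               0.90)
  ## audit identity: criterion equals the initial value times the exact
  ## product of step factors
  set.seed(9)
  st <- staircase_state(1.3)
  for (s in runif(12)) st <- update_staircase(st, s, "UP", cfg)
  expect_identical(st$criterion_mv, 1.3 * prod(st$step_factors))
})

test_that("sham schedule is fixed-rate, deterministic and measurement-independent", {
  s30 <- sham_schedule(30)
  expect_equal(sum(s30), 20L)                 # 66 % of 30
  expect_identical(s30, sham_schedule(30))    # no RNG involved
  expect_equal(sum(sham_schedule(100, 0.5)), 50L)
  set.seed(12)
  cors <- replicate(200, {
    meps <- rlnorm(30)
    suppressWarnings(cor(as.numeric(s30), meps))
  })
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("a training session has the protocol arithmetic and gated pre-rms", {
  p <- default_params
  pp <- make_participant(p)
  set.seed(21)
  cal <- quiet(calibrate_participant(p))
  cfg <- session_config(condition = "UP")
  ses <- run_session(pp, cfg, cal, day = "U1")
  tr <- ses$trials
  expect_equal(sum(tr$trial_type == "baseline_rest"), 20L)
  expect_equal(sum(tr$trial_type == "feedback"), 120L)
  expect_equal(sum(tr$trial_type == "post_rest"), 48L)
  ## gate postcondition: every logged pre-pulse rms below the threshold
  pre <- as.matrix(tr[, c("pre_rms_rfdi", "pre_rms_radm", "pre_rms_rop",
                          "pre_rms_lfdi")])
  expect_true(all(pre < cfg$gate_threshold))
  ## criterion audit trail: block criteria are the baseline mean times
  ## the cumulative staircase factors
  base <- mean(tr$mep_mv[tr$trial_type == "baseline_rest"])
  crit <- vapply(paste0("FB", 1:4), function(b) {
    unique(tr$criterion_mv[tr$block == b])
  }, numeric(1))
  expected <- base * cumprod(c(1, ses$staircase$step_factors[1:3]))
  expect_equal(unname(crit), expected)
})

test_that("control sessions reward on the sham schedule regardless of MEPs", {
  p <- default_params
  pp <- make_participant(p)
  set.seed(22)
  cal <- quiet(calibrate_participant(p))
  cfg <- session_config(condition = "UP", group = "control")
  ses <- run_session(pp, cfg, cal, day = "U1")
  fb <- ses$trials[ses$trials$trial_type == "feedback", ]
  sham <- sham_schedule(30, cfg$sham_rate)
  for (b in paste0("FB", 1:4)) {
    expect_identical(fb$rewarded[fb$block == b], sham)
  }
  expect_equal(ses$participant$skill_up, 0)   # no veridical learning
})

test_that("opposite-hemisphere blocks mix 20 + 20 trials with feedback on trained only", {
  p <- default_params
  pp <- make_trained_participant(p)
  set.seed(23)
  cal <- quiet(calibrate_participant(p))
  cfg <- session_config(condition = "UP")
  blk <- run_special_block(pp, cfg, cal, "opposite_hemisphere")
  tr <- blk$trials
  expect_equal(nrow(tr), 40L)
  expect_equal(sum(tr$hemisphere == "trained"), 20L)
  expect_equal(sum(tr$hemisphere == "opposite"), 20L)
  expect_true(all(is.na(tr$rewarded[tr$hemisphere == "opposite"])))
  expect_true(all(!is.na(tr$rewarded[tr$hemisphere == "trained"])))
  ## spillover: opposite-hemisphere MEPs modulated less than trained ones
  expect_lt(mean(tr$excitability[tr$hemisphere == "opposite"]),
            mean(tr$excitability[tr$hemisphere == "trained"]))
})

test_that("a full simulated course is bit-reproducible under the master seed", {
  a <- quiet(simulate_experiment(n_participants = 2, seed = 77,
                                 days = "U1", eeg_day = FALSE))
  b <- quiet(simulate_experiment(n_participants = 2, seed = 77,
                                 days = "U1", eeg_day = FALSE))
  expect_identical(a$trials, b$trials)
})

test_that("follow-up block variants keep timing but change feedback and skill", {
  p <- default_params
  set.seed(24)
  cal <- quiet(calibrate_participant(p))
  cfg <- session_config(condition = "UP")
  pp <- make_trained_participant(p)
  ff <- run_special_block(pp, cfg, cal, "feedback_free")
  expect_equal(nrow(ff$trials), 30L)
  expect_true(all(is.na(ff$trials$rewarded)))      # display suppressed
  expect_equal(ff$participant$skill_up, 1)         # no veridical learning
  ret <- run_special_block(pp, cfg, cal, "retention")
  expect_equal(nrow(ret$trials), 20L)
  expect_equal(unique(ret$trials$trial_type), "retention")
  ## skills decay to the retention fraction before the block
  expect_lte(ret$participant$skill_down, p$retention_frac)
  ## retained skill still modulates MEPs upward from baseline
  expect_gt(mean(ret$trials$mep_mv), cal$baseline_mean)
})
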