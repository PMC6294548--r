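test_that("REST pins expected excitability at 1 and asymptotes bound the range", {
  p <- default_params
  expect_equal(expected_excitability(latent_state("REST", 1, 1), p), 1)
  st_up <- latent_state("UP", skill_up = 1)
  expect_equal(expected_excitability(st_up, p), p$up_asymptote)
  st_dn <- latent_state("DOWN", skill_down = 1)
  expect_equal(expected_excitability(st_dn, p), p$down_asymptote)
  expect_gt(p$up_asymptote, 1)
  expect_lt(p$down_asymptote, 1)
  expect_gt(p$down_asymptote, 0)
})

test_that("skill grows only on veridically rewarded trials and is capped", {
  p <- default_params
  st <- latent_state("UP")
  set.seed(1)
  for (i in 1:120) st <- step_excitability(st, p, rewarded = TRUE,
                                           veridical = FALSE)
  expect_equal(st$skill_up, 0)        # sham reward: no learning
  for (i in 1:120) st <- step_excitability(st, p, rewarded = TRUE,
                                           veridical = TRUE)
  expect_equal(st$skill_up, 1)        # capped at 1
  st2 <- latent_state("DOWN")
  st2 <- step_excitability(st2, p, rewarded = FALSE, veridical = TRUE)
  expect_equal(st2$skill_down, 0)     # unrewarded: no learning
})

test_that("MEP generation follows the recruitment sigmoid", {
  p <- exact_params
  rest <- latent_state("REST")
  expect_equal(generate_mep(rest, p$i50, p), p$mep_max / 2)
  expect_equal(generate_mep(rest, 1e4, p), p$mep_max, tolerance = 1e-6)
  ## strictly increasing in intensity and excitability (in expectation)
  ints <- seq(30, 90, by = 5)
  means <- vapply(ints, function(i) generate_mep(rest, i, p), numeric(1))
  expect_true(all(diff(means) > 0))
  excs <- seq(0.8, 1.3, by = 0.05)
  m2 <- vapply(excs, function(e) {
    generate_mep(latent_state("REST", excitability = e), p$i50, p)
  }, numeric(1))
  expect_true(all(diff(m2) > 0))
})

test_that("multiplicative MEP noise has unit mean and the configured CV", {
  p <- default_params
  set.seed(7)
  draws <- generate_mep(latent_state("REST"), rep(p$i50, 1e4), p)
  expect_equal(mean(draws), p$mep_max / 2, tolerance = 0.02)
  expect_equal(stats::sd(draws) / mean(draws), p$mep_noise_cv,
               tolerance = 0.05)
})

test_that("background EMG has the resting rms level and tension breaks the gate", {
  p <- default_params
  set.seed(3)
  x <- generate_background_emg(p, duration_ms = 100)
  expect_equal(dim(x), c(200L, 4L))                  # 100 ms at 2000 Hz
  long <- generate_background_emg(p, duration_ms = 5000)
  win_rms <- vapply(seq(200, 10000, by = 200), function(i) {
    rms(long[(i - 199):i, 1])
  }, numeric(1))
  expect_gte(mean(win_rms >= 2 & win_rms <= 6), 0.95)
  tense <- generate_background_emg(p, 2000, tense = TRUE,
                                   tense_channels = 2)
  tense_rms <- vapply(seq(200, 4000, by = 100), function(i) {
    rms(tense[(i - 199):i, 2])
  }, numeric(1))
  expect_true(any(tense_rms > 7))
})

test_that("paired-pulse generation scales the single pulse by protocol ratios", {
  p <- exact_params
  rest <- latent_state("REST")
  sp <- generate_mep(rest, p$i50, p)
  sici <- pp_protocol("SICI", ts_intensity = p$i50)     # fixed rest ratio
  expect_equal(conditioned_mep(rest, sici, p) / sp, p$sici_ratio)
  lcd <- pp_protocol("LCD", ts_intensity = p$i50)
  expect_equal(conditioned_mep(rest, lcd, p) / sp, 1)   # LCD at rest: 100 %
  up <- latent_state("UP", skill_up = 1, params = p)
  sp_up <- generate_mep(up, p$i50, p)
  expect_equal(conditioned_mep(up, lcd, p) / sp_up, 1 + p$lcd_gain_up / 100)
  dn <- latent_state("DOWN", skill_down = 1, params = p)
  sp_dn <- generate_mep(dn, p$i50, p)
  expect_equal(conditioned_mep(dn, lcd, p) / sp_dn,
               1 + p$lcd_gain_down / 100)
})

test_that("identical seed and parameters reproduce draws bit for bit", {
  p <- default_params
  set.seed(11)
  a <- generate_mep(latent_state("REST"), rep(p$i50, 50), p)
  e1 <- generate_eeg_epoch(latent_state("UP", 1, 1), p, n_epochs = 3)
  set.seed(11)
  b <- generate_mep(latent_state("REST"), rep(p$i50, 50), p)
  e2 <- generate_eeg_epoch(latent_state("UP", 1, 1), p, n_epochs = 3)
  expect_identical(a, b)
  expect_identical(e1$data, e2$data)
})

test_that("asymptote calibration hits the target percent changes on the ideal curve", {
  p <- default_params
  base <- p$mep_max * stats::plogis(p$slope_k * (p$i50 - p$i50))
  up <- p$mep_max * stats::plogis(p$slope_k * (p$i50 * p$up_asymptote -
                                                 p$i50))
  dn <- p$mep_max * stats::plogis(p$slope_k * (p$i50 * p$down_asymptote -
                                                 p$i50))
  expect_equal(100 * (up - base) / base, 83.8, tolerance = 0.02)
  expect_equal(100 * (dn - base) / base, -30.6, tolerance = 0.02)
})
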