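test_that("the band-pass rejects movement-band drift and passes MEP frequencies", {
  fs <- 2000
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  slow <- sin(2 * pi * 10 * t)
  fast <- sin(2 * pi * 100 * t)
  mid <- 400:1600                         # avoid filter edge transients
  atten_db <- 20 * log10(rms(emg_bandpass(slow)[mid]) / rms(slow[mid]))
  expect_lt(atten_db, -20)
  pass_db <- 20 * log10(rms(emg_bandpass(fast)[mid]) / rms(fast[mid]))
  expect_lt(abs(pass_db), 1)
  expect_equal(emg_bandpass(rep(0, 1000)), rep(0, 1000))
})

test_that("background rms covers exactly the 110-10 ms pre-pulse window", {
  trace <- rep(0, 1000)
  pulse <- 600
  trace[(pulse - 220):(pulse - 21)] <- 5          # the 200-sample window
  expect_equal(background_rms(trace, pulse, filter = FALSE), 5)
  trace2 <- rep(c(3, -4), 500)
  expect_equal(background_rms(trace2, pulse, filter = FALSE),
               sqrt((9 + 16) / 2))
  ## samples outside the window do not contribute
  trace3 <- trace
  trace3[pulse - 10] <- 1e6
  expect_equal(background_rms(trace3, pulse, filter = FALSE), 5)
  expect_error(background_rms(trace, 100), "window")
})

test_that("peak-to-peak measures max minus min in mV and ignores the artifact", {
  trace <- rep(0, 600)
  pulse <- 300
  trace[pulse + 50] <- 1200                       # +1.2 mV
  trace[pulse + 60] <- -800                       # -0.8 mV
  expect_equal(peak_to_peak(trace, pulse, filter = FALSE), 2.0)
  expect_equal(peak_to_peak(rep(0, 600), pulse, filter = FALSE), 0)
  ## the 20-45 ms window excludes pulse-time samples by construction
  trace_art <- trace
  trace_art[pulse + (0:2)] <- c(9e5, -9e5, 5e5)
  expect_equal(peak_to_peak(trace_art, pulse, filter = FALSE), 2.0)
})

test_that("synthetic raw traces round-trip through the offline measurements", {
  p <- default_params
  set.seed(41)
  tr <- synth_mep_trace(2.0, p)
  expect_equal(peak_to_peak(tr$samples, tr$pulse_index), 2.0,
               tolerance = 0.05)
  bg <- background_rms(tr$samples, tr$pulse_index)
  expect_gt(bg, 2); expect_lt(bg, 6)
  ## tenfold artifact leaves the measured amplitude unchanged
  tr2 <- tr
  tr2$samples[tr$pulse_index + (0:2)] <-
    tr$samples[tr$pulse_index + (0:2)] * 10
  expect_equal(peak_to_peak(tr2$samples, tr2$pulse_index),
               peak_to_peak(tr$samples, tr$pulse_index))
})

test_that("block trimming removes exactly one maximum and one minimum", {
  expect_equal(trim_block_extremes(c(1, 2, 3)), c(FALSE, TRUE, FALSE))
  expect_equal(sum(trim_block_extremes(c(2, 2, 2))), 1L)   # ties: 2 removed
  expect_equal(sum(trim_block_extremes(rnorm(30))), 28L)
  expect_warning(trim_block_extremes(c(1, 2)), "fewer than 3")
})

test_that("the exclusion cascade applies its rules in order with one reason each", {
  ## absolute background rule
  cl <- apply_exclusions(bg_rms = c(12, 3, 3, 3, 3), trim = FALSE,
                         amplitude = rep(1, 5))
  expect_equal(cl$reason[1], "bg_abs")
  expect_true(all(cl$retained[-1]))
  ## interquartile fence, expected values from the linear-interpolation
  ## quartile convention (brute force: Q1 = 1, Q3 = 1.15, fence = 1.375)
  amps <- c(0.9, 1.0, 1.0, 1.05, 1.1, 1.2, 5.0)
  cl2 <- apply_exclusions(bg_rms = rep(3, 7), amplitude = amps,
                          trim = FALSE)
  expect_equal(cl2$reason, c(rep("none", 6), "amp_iqr"))
  ## clean homogeneous set: nothing excluded
  cl3 <- apply_exclusions(bg_rms = rep(3, 10), amplitude = rep(1, 10),
                          trim = FALSE)
  expect_true(all(cl3$retained))
  ## bookkeeping: one reason per trial, retained + excluded = total
  set.seed(8)
  cl4 <- apply_exclusions(bg_rms = runif(50, 2, 11),
                          amplitude = rlnorm(50),
                          block = rep(1:5, each = 10))
  expect_equal(sum(cl4$retained) + sum(!cl4$retained), 50L)
  expect_true(all(cl4$reason[cl4$retained] == "none"))
  expect_true(all(cl4$reason[!cl4$retained] != "none"))
})

test_that("rule one is idempotent on the retained set", {
  set.seed(9)
  bg <- runif(40, 2, 12)
  amp <- rlnorm(40)
  cl <- apply_exclusions(bg, amp, trim = FALSE)
  keep <- cl$retained
  cl2 <- apply_exclusions(bg[keep], amp[keep], trim = FALSE,
                          bg_sd_mult = Inf, iqr_mult = Inf)
  expect_true(all(cl2$retained))
})

test_that("percent change and modulation follow their definitions", {
  expect_equal(percent_change_from_baseline(1.838, 1.0), 83.8)
  expect_equal(percent_change_from_baseline(0.694, 1.0), -30.6)
  expect_equal(percent_change_from_baseline(2, 2), 0)
  expect_error(percent_change_from_baseline(1, 0), "positive")
  expect_equal(up_down_modulation(83.8, -30.6), 114.4)
  expect_equal(up_down_modulation(5, 5), 0)
  ## scale invariance
  set.seed(2)
  a <- rlnorm(30); b0 <- mean(rlnorm(20))
  expect_equal(percent_change_from_baseline(mean(a), b0),
               percent_change_from_baseline(mean(3.7 * a), 3.7 * b0))
})

test_that("Cohen's d matches its paired and pooled definitions", {
  set.seed(10)
  d <- rnorm(2e4, 0.5, 1)
  expect_equal(cohens_d(d), 0.5, tolerance = 0.05)
  x <- rnorm(2e4, 1); y <- rnorm(2e4, 0)
  expect_equal(cohens_d(x, y, type = "pooled"), 1, tolerance = 0.05)
  expect_error(cohens_d(rep(1, 5)), "zero variance")
  expect_error(cohens_d(1), "at least 2")
})
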