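test_that("pre-pulse epoch extraction is exact index arithmetic", {
  rec <- matrix(seq_len(6000), ncol = 1)
  ep <- extract_pre_tms_epoch(rec, pulse_index = 5000)
  expect_equal(dim(ep), c(1500L, 1L))
  expect_equal(ep[1, 1], 3500)
  expect_equal(ep[1500, 1], 4999)                 # ends one sample before
  ep2 <- extract_pre_tms_epoch(rec, pulse_index = 3000)
  expect_false(any(ep %in% ep2))                  # >= 1.5 s apart: disjoint
  expect_error(extract_pre_tms_epoch(rec, 1000), "insufficient")
})

test_that("the Welch estimator localizes tones and conserves power", {
  t <- seq(0, 1.499, by = 1e-3)
  sp <- welch_spectrum(sin(2 * pi * 20 * t))
  expect_equal(sp$freq[which.max(sp$power)], 20)
  ## Parseval: one-sided power sum of a unit tone ~ A^2/2
  expect_equal(sum(sp$power), 0.5, tolerance = 0.05)
  ## white noise: flat mean spectrum
  set.seed(14)
  xm <- matrix(rnorm(1500 * 1000), 1500, 1000)
  spm <- welch_spectrum(xm)
  mean_pw <- rowMeans(spm$power)[2:81]
  expect_lt(max(abs(mean_pw / mean(mean_pw) - 1)), 0.12)
  expect_equal(sum(rowMeans(spm$power)), 1, tolerance = 0.02)
})

test_that("relative power partitions 100 % across the eight bands", {
  freq <- 0:500
  flat <- rep(1, 501)
  rp <- relative_power(flat, freq)
  widths <- band_definitions()$hi - band_definitions()$lo + 1
  expect_equal(as.numeric(rp), 100 * widths / 80)
  expect_equal(sum(rp), 100)
  ## all power in the low-gamma band
  conc <- rep(0, 501); conc[freq %in% 31:50] <- 1
  rp2 <- relative_power(conc, freq)
  expect_equal(as.numeric(rp2["low_gamma"]), 100)
  expect_equal(sum(rp2[names(rp2) != "low_gamma"]), 0)
  expect_error(relative_power(rep(0, 501), freq), "zero total")
})

test_that("spectral features are invariant to per-epoch amplitude rescaling", {
  p <- default_params
  set.seed(15)
  ep <- generate_eeg_epoch(latent_state("REST"), p, n_epochs = 3)
  f1 <- band_power_features(ep$data[[1]])
  f2 <- band_power_features(ep$data[[1]] * 10)
  expect_equal(f1[, 1:17], f2[, 1:17], tolerance = 1e-10)
})

test_that("the low-gamma to high-alpha ratio follows its definition", {
  bpv <- stats::setNames(rep(12.5, 8), band_definitions()$band)
  expect_equal(gamma_alpha_ratio(bpv), 1.0)
  bpv["low_gamma"] <- 10; bpv["high_alpha"] <- 5
  expect_equal(gamma_alpha_ratio(bpv), 2.0)
  bpv["high_alpha"] <- 0
  expect_error(gamma_alpha_ratio(bpv), "positive")
})

test_that("1/f scaling flattens a 1/f spectrum and tilts a flat one", {
  freq <- 1:80
  bins_1f <- 100 * (1 / freq) / sum(1 / freq)
  scaled <- one_over_f_scale(bins_1f, freq)
  per_bin <- scaled / (band_definitions()$hi - band_definitions()$lo + 1)
  expect_lt(max(abs(per_bin / mean(per_bin) - 1)), 1e-10)  # exactly flat
  flat <- rep(100 / 80, 80)
  sflat <- one_over_f_scale(flat, freq)
  centers <- (band_definitions()$hi + band_definitions()$lo) / 2
  pb <- sflat / (band_definitions()$hi - band_definitions()$lo + 1)
  expect_equal(unname(pb / pb[1]), centers / centers[1], tolerance = 1e-10)
  ## 1/f^2 input: per-bin scaled power still decreases across bands
  bins_f2 <- 100 * (1 / freq^2) / sum(1 / freq^2)
  s2 <- one_over_f_scale(bins_f2, freq)
  pb2 <- s2 / (band_definitions()$hi - band_definitions()$lo + 1)
  expect_true(all(diff(unname(pb2)) < 0))
})

test_that("identical UP and DOWN sets give unit p-values and zero effects", {
  set.seed(16)
  half <- data.frame(subject = rep(1:6, each = 4),
                     condition = rep(c("UP", "DOWN"), 12))
  bands <- band_definitions()$band
  for (b in bands) half[[b]] <- rep(runif(6, 10, 14), each = 4)
  ct <- contrast_states(half)
  expect_true(all(ct$p == 1))
  expect_true(all(ct$p_fdr == 1))
  expect_true(all(ct$delta_pct == 0))
  expect_true(all(ct$p_fdr >= ct$p))            # FDR never lowers a p
})

test_that("contrasts on generator cohorts flag the prescribed bands with correct signs", {
  feats <- trained_features(n_subjects = 8, seed = 51)
  ct <- contrast_states(feats)
  expect_true(all(ct$p_fdr >= ct$p - 1e-12))
  sig <- ct$p_fdr < 0.05
  expect_true(sig[ct$band == "theta"])
  expect_true(sig[ct$band == "high_gamma"])
  expect_lt(ct$delta_pct[ct$band == "theta"], 0)
  expect_lt(ct$delta_pct[ct$band == "low_alpha"], 0)
  expect_gt(ct$delta_pct[ct$band == "low_gamma"], 0)
  expect_gt(ct$delta_pct[ct$band == "high_gamma"], 0)
  ## betas carry no programmed effect
  expect_false(sig[ct$band == "low_beta"])
  expect_false(sig[ct$band == "high_beta"])
})

test_that("false-positive rate of the null band contrast is controlled", {
  set.seed(17)
  n_sig <- replicate(60, {
    f <- data.frame(subject = rep(1:10, each = 8),
                    condition = rep(c("UP", "DOWN"), 40))
    for (b in band_definitions()$band) f[[b]] <- rnorm(80, 12, 2)
    sum(contrast_states(f)$p_fdr < 0.05)
  })
  expect_lt(mean(n_sig > 0), 0.12)
})

test_that("trial-wise robust regression recovers exact linear structure", {
  set.seed(18)
  f <- data.frame(subject = 1)[rep(1, 120), , drop = FALSE]
  for (b in paste0("scaled_", band_definitions()$band)) {
    f[[b]] <- runif(120, 5, 15)
  }
  f$ratio <- runif(120, 0.5, 2)
  f$mep_mv <- 2 * f$scaled_theta + rnorm(120, 0, 1e-8)
  f2 <- f; f2$subject <- 2
  rr <- trialwise_regression(rbind(f, f2))
  expect_equal(unname(rr$group$median_slope[
    rr$group$predictor == "scaled_theta"]), 2, tolerance = 1e-4)
  others <- rr$group$median_slope[!rr$group$predictor %in%
                                    c("scaled_theta", "ratio")]
  expect_lt(max(abs(others)), 1e-4)
  ## degenerate designs are rejected with a diagnostic
  f3 <- rbind(f, f2)
  f3$scaled_delta <- f3$scaled_theta
  expect_error(trialwise_regression(f3), "rank-deficient")
})

test_that("slopes are null when amplitudes are independent of band power", {
  set.seed(19)
  frac_sig <- replicate(30, {
    f <- do.call(rbind, lapply(1:10, function(s) {
      g <- data.frame(subject = s)[rep(1, 40), , drop = FALSE]
      for (b in paste0("scaled_", band_definitions()$band)) {
        g[[b]] <- runif(40, 5, 15)
      }
      g$ratio <- runif(40, 0.5, 2)
      g$mep_mv <- rlnorm(40)
      g
    }))
    rr <- trialwise_regression(f)
    mean(rr$group$p_fdr < 0.05)
  })
  expect_lt(mean(frac_sig), 0.08)
})

test_that("generator coupling yields negative alpha and positive gamma slopes", {
  feats <- trained_features(n_subjects = 8, seed = 52, attach_mep = TRUE)
  rr <- trialwise_regression(feats)
  g <- rr$group
  expect_lt(g$median_slope[g$predictor == "scaled_high_alpha"], 0)
  expect_lt(g$median_slope[g$predictor == "scaled_low_alpha"], 0)
  expect_gt(g$median_slope[g$predictor == "scaled_low_gamma"], 0)
  expect_gt(g$median_slope[g$predictor == "scaled_high_gamma"], 0)
  expect_gt(g$median_slope[g$predictor == "ratio"], 0)
})
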