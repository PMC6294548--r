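## eeg_features: pre-stimulus spectral pipeline ------------------------------

#' Extract the 1.5 s pre-pulse EEG epoch
#'
#' Returns the 1500 samples (per channel) ending one sample before the
#' pulse -- no post-pulse data ever enters the epoch.
#'
#' @param recording numeric matrix, samples x channels, at 1000 Hz.
#' @param pulse_index sample index of the TMS pulse.
#' @param fs sampling rate (Hz).
#' @return A samples x channels matrix of the pre-pulse window.
#' @export
extract_pre_tms_epoch <- function(recording, pulse_index, fs = 1000) {
  n <- round(1.5 * fs)
  if (pulse_index - n < 1) {
    stop("insufficient pre-pulse data for a 1.5 s epoch")
  }
  recording <- as.matrix(recording)
  recording[(pulse_index - n):(pulse_index - 1L), , drop = FALSE]
}

#' Relative band power of one spectrum
#'
#' Expresses the power of each frequency bin as a percentage of the total
#' power over the analyzed 1--80 Hz range, then sums within the eight
#' bands. The eight band percentages partition 100 %.
#'
#' @param power spectrum power vector (or matrix, one spectrum per
#'   column) over frequencies `freq`.
#' @param freq frequency axis in Hz.
#' @param fmin,fmax analyzed range (Hz, inclusive).
#' @return A named 8-vector of band percentages (or an 8 x n matrix), with
#'   attribute `"bins_pct"` holding the per-bin relative power.
#' @export
relative_power <- function(power, freq, fmin = 1, fmax = 80) {
  pm <- if (is.matrix(power)) power else matrix(power, ncol = 1)
  sel <- freq >= fmin & freq <= fmax
  pm <- pm[sel, , drop = FALSE]
  tot <- colSums(pm)
  if (any(tot <= 0)) stop("zero total power in analyzed range")
  bins <- 100 * sweep(pm, 2, tot, `/`)
  bb <- band_of_bin(freq[sel])
  bands <- apply(bins, 2, function(col) {
    out <- numeric(8)
    sums <- tapply(col, bb, sum)
    out[as.integer(names(sums))] <- sums
    out
  })
  rownames(bands) <- band_names()
  res <- if (is.matrix(power)) bands else {
    stats::setNames(bands[, 1], band_names())
  }
  attr(res, "bins_pct") <- if (is.matrix(power)) bins else bins[, 1]
  attr(res, "bin_freq") <- freq[sel]
  res
}

#' Low-gamma to high-alpha ratio
#'
#' @param bpv a band-power vector (or 8 x n matrix) from
#'   [relative_power()].
#' @return `low_gamma / high_alpha`.
#' @export
gamma_alpha_ratio <- function(bpv) {
  if (is.matrix(bpv)) {
    ha <- bpv["high_alpha", ]; lg <- bpv["low_gamma", ]
  } else {
    ha <- bpv[["high_alpha"]]; lg <- bpv[["low_gamma"]]
  }
  if (any(ha <= 0)) stop("high_alpha power must be positive")
  lg / ha
}

#' 1/f scaling of relative power
#'
#' Whitens the spectrum against a 1/f background by multiplying each
#' bin's relative power by its frequency (raised to `exponent`) before
#' band aggregation. An exact `1/f` spectrum becomes flat under the
#' default.
#'
#' @param bins_pct per-bin relative power (vector or bins x n matrix).
#' @param freq bin frequencies (Hz).
#' @param exponent scaling exponent (1 = multiply by f).
#' @return Scaled per-band sums (8-vector or 8 x n matrix).
#' @export
one_over_f_scale <- function(bins_pct, freq, exponent = 1) {
  bm <- if (is.matrix(bins_pct)) bins_pct else matrix(bins_pct, ncol = 1)
  scaled <- bm * freq^exponent
  bb <- band_of_bin(freq)
  bands <- apply(scaled, 2, function(col) {
    out <- numeric(8)
    sums <- tapply(col, bb, sum)
    out[as.integer(names(sums))] <- sums
    out
  })
  rownames(bands) <- band_names()
  if (is.matrix(bins_pct)) bands else stats::setNames(bands[, 1],
                                                      band_names())
}

#' Band-power feature table of an epoch set
#'
#' Runs the Welch/relative-power pipeline on every epoch of the chosen
#' channel and returns the per-epoch feature rows used by the contrasts,
#' the trial-wise regression and the classifier: the eight relative band
#' powers (%), the low-gamma:high-alpha ratio, and the 1/f-scaled band
#' powers.
#'
#' @param epochs an `eeg_epochs` object (see [generate_eeg_epoch()]) or a
#'   samples x epochs matrix.
#' @param channel channel to analyze (default: the hotspot).
#' @param condition optional per-epoch condition labels (defaults to the
#'   epochs' strategies).
#' @return A data frame with columns `condition`, the 8 band names, `ratio`
#'   and `scaled_<band>` columns.
#' @export
band_power_features <- function(epochs, channel = NULL, condition = NULL) {
  if (inherits(epochs, "eeg_epochs")) {
    ch <- channel %||% epochs$hotspot
    x <- epochs$data[[ch]]
    condition <- condition %||% epochs$strategy
  } else {
    x <- as.matrix(epochs)
  }
  sp <- welch_spectrum(x)
  rp <- relative_power(sp$power, sp$freq)
  bins <- attr(rp, "bins_pct")
  scl <- one_over_f_scale(bins, attr(rp, "bin_freq"))
  out <- as.data.frame(t(rp))
  out$ratio <- gamma_alpha_ratio(rp)
  scl_df <- as.data.frame(t(scl))
  names(scl_df) <- paste0("scaled_", names(scl_df))
  out <- cbind(out, scl_df)
  out$condition <- if (is.null(condition)) NA_character_ else
    rep_len(condition, nrow(out))
  out
}

#' Paired UP-vs-DOWN band-power contrast
#'
#' For each band: Wilcoxon signed-rank test on the per-subject UP-minus-
#' DOWN means of relative power, Benjamini-Hochberg adjustment across the
#' tested bands, the subject-level paired effect size, and the mean
#' within-subject epoch-level standardized difference (the generator's
#' calibration target).
#'
#' @param features a feature data frame from [band_power_features()] with
#'   a `subject` column and `condition` in `{"UP", "DOWN"}`.
#' @param bands feature columns to contrast.
#' @return A data frame of class `contrast_result`: `band`, `delta_pct`
#'   (mean UP-DOWN difference), `statistic`, `p`, `p_fdr`, `d_subject`,
#'   `d_epoch`.
#' @export
contrast_states <- function(features, bands = band_names()) {
  stopifnot(!is.null(features$subject), !is.null(features$condition))
  subjects <- unique(features$subject)
  if (length(subjects) < 6) stop("need at least 6 paired subjects")
  res <- lapply(bands, function(b) {
    diffs <- vapply(subjects, function(s) {
      g <- features[features$subject == s, ]
      mean(g[[b]][g$condition == "UP"]) -
        mean(g[[b]][g$condition == "DOWN"])
    }, numeric(1))
    d_ep <- vapply(subjects, function(s) {
      g <- features[features$subject == s, ]
      x <- g[[b]][g$condition == "UP"]; y <- g[[b]][g$condition == "DOWN"]
      if (stats::sd(c(x, y)) == 0) return(0)
      cohens_d(x, y, type = "pooled")
    }, numeric(1))
    if (all(diffs == 0)) {
      return(data.frame(band = b, delta_pct = 0, statistic = NA_real_,
                        p = 1, d_subject = 0, d_epoch = mean(d_ep),
                        stringsAsFactors = FALSE))
    }
    wt <- stats::wilcox.test(diffs, exact = FALSE)
    data.frame(band = b, delta_pct = mean(diffs),
               statistic = unname(wt$statistic), p = wt$p.value,
               d_subject = mean(diffs) / stats::sd(diffs),
               d_epoch = mean(d_ep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("band", "delta_pct", "statistic", "p", "p_fdr",
                 "d_subject", "d_epoch")]
  class(out) <- c("contrast_result", class(out))
  out
}

#' Trial-wise robust regression of MEP amplitude on band power
#'
#' Per subject: iteratively reweighted robust linear fit ([MASS::rlm],
#' Huber loss) of single-trial MEP amplitude on the eight band powers
#' (and separately on the low-gamma:high-alpha ratio). Per-subject slopes
#' are aggregated with Wilcoxon signed-rank tests against 0 and FDR
#' correction.
#'
#' The joint model uses the 1/f-scaled band powers by default: the raw
#' relative powers partition 100 % exactly, so a joint design containing
#' all eight raw bands plus an intercept is singular by construction;
#' the scaled sums carry no such constraint.
#'
#' @param features feature data frame with `subject`, band columns,
#'   `ratio` and `mep_mv`.
#' @param predictors predictor columns for the joint model.
#' @return A list of class `regression_result` with `slopes` (subjects x
#'   predictors), `ratio_slopes`, and `group` (per-predictor median slope,
#'   p, p_fdr).
#' @export
trialwise_regression <- function(features,
                                 predictors = paste0("scaled_",
                                                     band_names())) {
  stopifnot(!is.null(features$subject), !is.null(features$mep_mv))
  subjects <- unique(features$subject)
  fit_one <- function(g) {
    X <- as.matrix(g[, predictors, drop = FALSE])
    if (nrow(X) < 2 * (ncol(X) + 1)) {
      stop("need at least twice as many trials as predictors")
    }
    if (qr(cbind(1, X))$rank < ncol(X) + 1) {
      stop("rank-deficient design: collinear band powers")
    }
    fit <- MASS::rlm(stats::reformulate(predictors, "mep_mv"), data = g,
                     maxit = 100)
    rfit <- MASS::rlm(mep_mv ~ ratio, data = g, maxit = 100)
    list(beta = stats::coef(fit)[-1], ratio = stats::coef(rfit)[2])
  }
  fits <- lapply(subjects, function(s) {
    fit_one(features[features$subject == s, ])
  })
  slopes <- do.call(rbind, lapply(fits, `[[`, "beta"))
  rownames(slopes) <- subjects
  colnames(slopes) <- predictors
  ratio_slopes <- vapply(fits, `[[`, numeric(1), "ratio")
  test_col <- function(v) {
    if (all(v == 0)) return(1)
    stats::wilcox.test(v, exact = FALSE)$p.value
  }
  pg <- apply(slopes, 2, test_col)
  p_ratio <- test_col(ratio_slopes)
  group <- data.frame(predictor = c(predictors, "ratio"),
                      median_slope = c(apply(slopes, 2, stats::median),
                                       stats::median(ratio_slopes)),
                      p = c(pg, p_ratio), stringsAsFactors = FALSE)
  group$p_fdr <- stats::p.adjust(group$p, method = "BH")
  structure(list(slopes = slopes, ratio_slopes = ratio_slopes,
                 group = group), class = "regression_result")
}
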