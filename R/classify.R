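## classification: linear maximum-margin state decoding ----------------------
##
## Linear SVM (C = 1) via e1071, stratified 10-fold cross-validation with
## within-training-fold standardization (no information leak), permutation
## null with the identical pipeline, and recursive feature elimination on
## the margin weights.

## Stratified fold assignment, reproducible from the current RNG stream.
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

## Linear SVM weight vector on (already standardized) training data.
svm_weights <- function(fit) {
  drop(crossprod(fit$coefs, fit$SV))
}

#' Cross-validated linear SVM classification
#'
#' Stratified k-fold cross-validation of a linear support vector machine
#' (cost `C = 1`). Features are z-scored using training-fold statistics
#' only; the test fold is scaled with the same statistics.
#'
#' @param x numeric feature matrix (trials x features).
#' @param y class labels (two classes, balanced recommended).
#' @param folds number of folds.
#' @param cost SVM margin parameter.
#' @param seed RNG seed for the fold assignment.
#' @param scale logical; standardize within training folds.
#' @return A list of class `cv_result`: `fold_accuracy` (%), `accuracy`
#'   (mean %, `folds`, `cost`).
#' @export
crossval_classify <- function(x, y, folds = 10, cost = 1, seed = 1,
                              scale = TRUE) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- factor(y)
  stopifnot(nlevels(y) == 2, min(table(y)) >= folds)
  set.seed(seed)
  fold <- stratified_folds(y, folds)
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    xtr <- x[tr, , drop = FALSE]; xte <- x[!tr, , drop = FALSE]
    if (scale) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, `/`)
      xte <- sweep(sweep(xte, 2, mu), 2, sdv, `/`)
    }
    fit <- e1071::svm(xtr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    100 * mean(stats::predict(fit, xte) == y[!tr])
  }, numeric(1))
  structure(list(fold_accuracy = acc, accuracy = mean(acc),
                 folds = folds, cost = cost), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold linear SVM (C = %g): %.1f %% accuracy\n",
              x$folds, x$cost, x$accuracy))
  invisible(x)
}

#' Permutation null distribution of the CV accuracy
#'
#' Repeats the identical cross-validation pipeline with randomly permuted
#' labels and reports the rank-based p-value of the true accuracy,
#' `(1 + #{null >= true}) / (n_perm + 1)`.
#'
#' @param x,y as in [crossval_classify()].
#' @param n_perm number of permutations (>= 100 recommended).
#' @param folds,cost,seed as in [crossval_classify()].
#' @return A list of class `null_distribution`: `null_accuracy` (%),
#'   `true_accuracy`, `p`.
#' @export
permutation_null <- function(x, y, n_perm = 100, folds = 10, cost = 1,
                             seed = 1) {
  true <- crossval_classify(x, y, folds, cost, seed)$accuracy
  seeds <- derive_seeds(seed, n_perm, salt = 1L)
  null <- vapply(seq_len(n_perm), function(i) {
    set.seed(seeds[i])
    yp <- sample(y)
    crossval_classify(x, yp, folds, cost, seed = seeds[i])$accuracy
  }, numeric(1))
  p <- (1 + sum(null >= true)) / (n_perm + 1)
  structure(list(null_accuracy = null, true_accuracy = true, p = p),
            class = "null_distribution")
}

#' Feature ranking by recursive feature elimination
#'
#' Iteratively fits the linear SVM on standardized data and removes the
#' feature with the smallest absolute margin weight until one remains
#' (ties broken toward the later column, so earlier columns rank higher).
#' The reversed elimination order is the ranking.
#'
#' @param x feature matrix (trials x features, named columns).
#' @param y class labels.
#' @param cost SVM margin parameter.
#' @return An integer ranking vector of class `feature_ranking`
#'   (`ranking[1]` = index of the top feature), named by feature.
#' @export
rfe_rank <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(y)
  active <- seq_len(ncol(x))
  elim <- integer(0)
  while (length(active) > 1) {
    xa <- x[, active, drop = FALSE]
    sdv <- apply(xa, 2, stats::sd)
    sdv[sdv == 0] <- 1
    xa <- sweep(sweep(xa, 2, colMeans(xa)), 2, sdv, `/`)
    fit <- e1071::svm(xa, y, kernel = "linear", cost = cost,
                      scale = FALSE)
    w <- abs(svm_weights(fit))
    w[apply(x[, active, drop = FALSE], 2, stats::sd) == 0] <- -Inf
    drop_i <- max(which(w == min(w)))          # tie: drop later column
    elim <- c(elim, active[drop_i])
    active <- active[-drop_i]
  }
  ranking <- rev(c(elim, active))
  names(ranking) <- colnames(x)[ranking]
  class(ranking) <- "feature_ranking"
  ranking
}

#' Aggregate per-subject feature rankings
#'
#' For each rank position the modal feature across subjects is taken;
#' conflicts (a feature already assigned to a better rank) and ties are
#' resolved by the feature's mean rank across subjects.
#'
#' @param rankings a list of rankings from [rfe_rank()] (or a matrix with
#'   one subject per row, entries = feature index at each rank position).
#' @return Integer vector: the consensus ranking (a permutation of the
#'   features), named if the inputs were named.
#' @export
aggregate_rankings <- function(rankings) {
  if (is.list(rankings)) {
    rankings <- do.call(rbind, lapply(rankings, as.integer))
  }
  stopifnot(nrow(rankings) >= 2)
  nf <- ncol(rankings)
  ## mean rank position of each feature
  pos <- matrix(NA_real_, nrow(rankings), nf)
  for (i in seq_len(nrow(rankings))) pos[i, rankings[i, ]] <- seq_len(nf)
  mean_rank <- colMeans(pos)
  out <- integer(0)
  for (r in seq_len(nf)) {
    cand <- rankings[, r]
    cand <- cand[!cand %in% out]
    if (!length(cand)) {
      pick <- setdiff(order(mean_rank), out)[1]
    } else {
      tab <- table(cand)
      best <- as.integer(names(tab)[tab == max(tab)])
      pick <- best[order(mean_rank[best])][1]
    }
    out <- c(out, pick)
  }
  out
}
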