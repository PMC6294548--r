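#' Root mean square
#'
#' @param x numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

## Derive a stream of child seeds from a master seed; kept < 2^31 so they are
## valid R integer seeds.
derive_seeds <- function(seed, n, salt = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m)
  vapply(seq_len(n), function(i) {
    as.integer((s * 48271 + i * 104729 + salt * 7919) %% m)
  }, integer(1))
}

## Multiplicative log-normal noise with mean 1 and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
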