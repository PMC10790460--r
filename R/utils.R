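## Internal weighted-moment helpers. All use population (not n-1) normalization:
## the fractional-rank construction assumes population CDF weights, and the
## concentration-index covariance must match it.

w_default <- function(x, weights) {
  if (is.null(weights)) rep(1, length(x)) else weights
}

check_weights <- function(weights, n) {
  if (length(weights) != n) {
    stop("weights must have length ", n, ", got ", length(weights), call. = FALSE)
  }
  if (anyNA(weights) || any(weights <= 0)) {
    stop("weights must be positive and non-missing", call. = FALSE)
  }
  invisible(weights)
}

weighted_mean <- function(x, weights = NULL) {
  w <- w_default(x, weights)
  sum(w * x) / sum(w)
}

## Population-normalized weighted variance: sum w (x - xbar)^2 / sum w
weighted_var <- function(x, weights = NULL) {
  w <- w_default(x, weights)
  m <- sum(w * x) / sum(w)
  sum(w * (x - m)^2) / sum(w)
}

## Population-normalized weighted covariance
weighted_cov <- function(x, y, weights = NULL) {
  w <- w_default(x, weights)
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sum(w * (x - mx) * (y - my)) / sum(w)
}

## Kish effective sample size (sum w)^2 / sum w^2; equals n for equal weights
effective_n <- function(weights) {
  sum(weights)^2 / sum(weights^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
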