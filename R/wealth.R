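#' Asset-based socioeconomic score
#'
#' First principal component of the standardized household asset indicators
#' (correlation-matrix PCA), the usual proxy for household wealth in surveys
#' without income data. Assets are standardized to mean 0 / variance 1 so
#' that rare and common assets contribute on the same scale. The score's
#' sign is arbitrary in PCA, so it is oriented to correlate positively with
#' a declared "privileged" asset — by default the asset with the largest
#' absolute loading — making higher scores mean better-off.
#'
#' @param assets numeric matrix or data frame, one column per asset
#'   indicator (binary or real), one row per household/child.
#' @param weights optional positive row weights; when supplied the PCA uses
#'   the weighted covariance of the standardized assets.
#' @param orient_asset column name (or index) of the asset whose loading is
#'   forced positive; default: the asset with the largest absolute loading.
#' @return list of class `wealth_result`: `ses_score`, `ses_quintile`
#'   (1 = poorest fifth of total weight, 5 = richest), `loadings`,
#'   `explained_share` and the columns dropped for zero variance.
#' @export
wealth_scores <- function(assets, weights = NULL, orient_asset = NULL) {
  A <- as.matrix(assets)
  if (is.null(colnames(A))) colnames(A) <- paste0("asset", seq_len(ncol(A)))
  storage.mode(A) <- "double"
  if (anyNA(A)) stop("missing values in asset matrix", call. = FALSE)
  n <- nrow(A)
  w <- w_default(A[, 1], weights)
  check_weights(w, n)

  sds <- apply(A, 2, function(x) sqrt(weighted_var(x, w)))
  dropped <- colnames(A)[sds == 0]
  if (length(dropped) == ncol(A)) {
    stop("no asset variance: all asset columns are constant", call. = FALSE)
  }
  if (length(dropped) > 0) {
    warning("dropping constant asset column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    A <- A[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }

  mus <- apply(A, 2, function(x) weighted_mean(x, w))
  Z <- sweep(sweep(A, 2, mus, "-"), 2, sds, "/")

  if (ncol(Z) == 1) {
    score <- Z[, 1]
    loadings <- stats::setNames(1, colnames(Z))
    explained <- 1
  } else {
    ## weighted correlation-matrix PCA via eigendecomposition
    Wn <- w / sum(w)
    C <- crossprod(Z * sqrt(Wn), Z * sqrt(Wn))
    eig <- eigen(C, symmetric = TRUE)
    loadings <- stats::setNames(eig$vectors[, 1], colnames(Z))
    explained <- eig$values[1] / sum(eig$values)
    score <- as.numeric(Z %*% loadings)
  }

  ## deterministic sign convention
  anchor <- if (is.null(orient_asset)) {
    names(loadings)[which.max(abs(loadings))]
  } else {
    if (is.numeric(orient_asset)) orient_asset <- colnames(Z)[orient_asset]
    if (!orient_asset %in% names(loadings)) {
      stop("orientation asset '", orient_asset, "' not among (non-constant) assets",
           call. = FALSE)
    }
    orient_asset
  }
  if (loadings[[anchor]] < 0) {
    loadings <- -loadings
    score <- -score
  }

  ## quintiles cut on the score rounded to 9 decimals: scores equal up to
  ## eigensolver floating noise must land in the same tie group
  structure(list(ses_score = score,
                 ses_quintile = weighted_quintiles(round(score, 9), w),
                 loadings = loadings,
                 explained_share = explained,
                 dropped = dropped),
            class = "wealth_result")
}

#' @export
print.wealth_result <- function(x, ...) {
  cat("Asset-based wealth index (first principal component)\n")
  cat("  variance explained:", sprintf("%.1f%%", 100 * x$explained_share), "\n")
  cat("  loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Weighted quintile assignment
#'
#' Cuts a score into fifths of total weight: boundaries at cumulative-weight
#' fractions 0.2/0.4/0.6/0.8, tied scores sharing the quintile of their tie
#' group's midpoint cumulative weight (so ties never straddle a boundary).
#'
#' @param score numeric vector.
#' @param weights positive weights, default all 1.
#' @return integer vector in 1..5, in input order.
#' @export
weighted_quintiles <- function(score, weights = NULL) {
  if (length(score) == 0) stop("empty input to weighted_quintiles", call. = FALSE)
  rank_quintile(fractional_rank(score, weights))
}
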