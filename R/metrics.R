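#' Wagstaff concentration index
#'
#' Twice the weighted population covariance between the observed binary
#' outcome and the fractional rank of the ranking variable, scaled by mean
#' coverage:
#' \deqn{CI_W = \frac{2}{\mu} \mathrm{Cov}(y, F)}
#' Positive values mean the outcome is concentrated among the higher-ranked
#' (more privileged under the composite ranking, richer under a wealth
#' ranking); negative values mean pro-disadvantaged / pro-poor.
#'
#' @param y binary outcome vector (0/1).
#' @param frank fractional ranks in (0,1), e.g. from [fractional_rank()].
#' @param weights positive weights, default all 1.
#' @return scalar concentration index.
#' @examples
#' wagstaff_ci(c(0, 0, 1, 1, 1), c(0.1, 0.3, 0.5, 0.7, 0.9))  # 0.4
#' @export
wagstaff_ci <- function(y, frank, weights = NULL) {
  w <- w_default(y, weights)
  check_weights(w, length(y))
  mu <- weighted_mean(y, w)
  if (mu <= 0) {
    stop("concentration index undefined: mean coverage is zero", call. = FALSE)
  }
  2 / mu * weighted_cov(y, frank, w)
}

#' Erreygers-corrected concentration index
#'
#' Rescales the Wagstaff index for a bounded (binary) outcome:
#' \deqn{CI_E = 4 \mu \, CI_W}
#' The correction makes indices comparable across outcomes with different
#' mean coverage; note that for rare outcomes the two indices can differ by
#' an order of magnitude while sharing a sign.
#'
#' @param mu mean coverage in \[0, 1\].
#' @param ci_wagstaff Wagstaff index.
#' @return scalar corrected index.
#' @examples
#' erreygers_ci(0.6, 0.4)  # 0.96
#' @export
erreygers_ci <- function(mu, ci_wagstaff) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]", call. = FALSE)
  4 * mu * ci_wagstaff
}

#' Absolute equity gap
#'
#' Weighted coverage in the top 20% of the ranking distribution minus the
#' bottom 20%: the coverage increase the most disadvantaged quintile would
#' need to match the most privileged quintile. Quintile membership comes from
#' cumulative-weight cuts of the fractional rank.
#'
#' @inheritParams wagstaff_ci
#' @return list with `aeg` (scalar) and `quintile_summary`, a data frame with
#'   one row per rank quintile: effective n, total weight, weighted coverage
#'   and within-quintile outcome variance (used by [aeg_confidence_bounds()]).
#' @export
absolute_equity_gap <- function(y, frank, weights = NULL) {
  w <- w_default(y, weights)
  check_weights(w, length(y))
  q <- rank_quintile(frank)
  qs <- do.call(rbind, lapply(1:5, function(k) {
    idx <- q == k
    if (!any(idx)) {
      return(data.frame(quintile = k, n = 0, n_eff = 0, weight = 0,
                        coverage = NA_real_, s2 = NA_real_))
    }
    data.frame(quintile = k,
               n = sum(idx),
               n_eff = effective_n(w[idx]),
               weight = sum(w[idx]),
               coverage = weighted_mean(y[idx], w[idx]),
               s2 = weighted_var(y[idx], w[idx]))
  }))
  if (qs$n[qs$quintile == 1] == 0 || qs$n[qs$quintile == 5] == 0) {
    stop("empty extreme rank quintile: absolute equity gap undefined",
         call. = FALSE)
  }
  aeg <- qs$coverage[qs$quintile == 5] - qs$coverage[qs$quintile == 1]
  list(aeg = aeg, quintile_summary = qs)
}

#' Confidence bounds for a concentration index
#'
#' Symmetric 95% bounds `ci +/- 1.96 * half_width`. Two modes:
#' \describe{
#'   \item{`"estimator"` (default)}{half-width `1.96 * sqrt(Var(y) / n_eff)`
#'     with `n_eff = (sum w)^2 / sum w^2`, i.e. the standard error of mean
#'     coverage under the survey weights. This tracks the width of published
#'     coverage intervals.}
#'   \item{`"as_printed"`}{half-width `1.96 * sqrt(Var(y))` with no sample-size
#'     scaling — the literal population-variance formula sometimes quoted for
#'     these indices; it yields very wide intervals and is provided for
#'     comparability.}
#' }
#'
#' @param ci the index the interval is centred on.
#' @param y binary outcome vector.
#' @param weights positive weights.
#' @param mode `"estimator"` or `"as_printed"`.
#' @return numeric `c(low, high)`.
#' @export
ci_confidence_bounds <- function(ci, y, weights = NULL,
                                 mode = c("estimator", "as_printed")) {
  mode <- match.arg(mode)
  n <- length(y)
  if (n < 2) stop("need at least 2 observations for confidence bounds",
                  call. = FALSE)
  w <- w_default(y, weights)
  check_weights(w, n)
  v <- weighted_var(y, w)
  half <- if (mode == "as_printed") 1.96 * sqrt(v)
          else 1.96 * sqrt(v / effective_n(w))
  c(ci - half, ci + half)
}

#' Confidence bounds for the absolute equity gap
#'
#' `AEG +/- 1.96 * sqrt(s5^2/n5 + s1^2/n1)` using the within-quintile outcome
#' variances and effective sizes of the extreme rank quintiles.
#'
#' @param aeg the gap the interval is centred on.
#' @param quintile_summary the data frame from [absolute_equity_gap()].
#' @return numeric `c(low, high)`.
#' @examples
#' qs <- data.frame(quintile = c(1, 5), n = c(100, 100), n_eff = c(100, 100),
#'                  weight = c(100, 100), coverage = c(0.5, 0.9),
#'                  s2 = c(0.25, 0.09))
#' aeg_confidence_bounds(0.4, qs)  # (0.286, 0.514)
#' @export
aeg_confidence_bounds <- function(aeg, quintile_summary) {
  qs <- quintile_summary
  q1 <- qs[qs$quintile == 1, ]
  q5 <- qs[qs$quintile == 5, ]
  if (nrow(q1) == 0 || nrow(q5) == 0 || q1$n < 2 || q5$n < 2) {
    stop("extreme quintiles must each contain at least 2 observations",
         call. = FALSE)
  }
  half <- 1.96 * sqrt(q5$s2 / q5$n_eff + q1$s2 / q1$n_eff)
  c(aeg - half, aeg + half)
}

#' Equity level
#'
#' One minus the absolute value of the Wagstaff concentration index: 1 is
#' perfect equity, lower values more inequity (in either direction).
#'
#' @param ci_wagstaff Wagstaff index (scalar or vector).
#' @param digits decimals for report tables (default 2); `NULL` for the raw
#'   value.
#' @return numeric equity level(s).
#' @examples
#' equity_level(0.150)  # 0.85
#' equity_level(-0.054) # 0.95
#' @export
equity_level <- function(ci_wagstaff, digits = 2) {
  lev <- 1 - abs(ci_wagstaff)
  if (is.null(digits)) lev else round(lev, digits)
}

#' Concentration curve
#'
#' Cumulative population share (ranked by fractional rank, least privileged
#' first) against cumulative share of the outcome. The curve runs from (0,0)
#' to (1,1); lying below the 45-degree diagonal means the outcome is
#' concentrated among the higher-ranked. Twice the area between the curve and
#' the diagonal (trapezoid rule over the tie-group points) equals the
#' Wagstaff index computed from the covariance formula.
#'
#' @inheritParams wagstaff_ci
#' @return data frame with columns `pop_share` and `outcome_share`, one row
#'   per tie group of the ranking plus the (0,0) origin.
#' @export
concentration_curve <- function(y, frank, weights = NULL) {
  w <- w_default(y, weights)
  check_weights(w, length(y))
  if (weighted_mean(y, w) <= 0) {
    stop("concentration curve undefined: mean coverage is zero", call. = FALSE)
  }
  ord <- order(frank)
  f_s <- frank[ord]; y_s <- y[ord]; w_s <- w[ord]
  grp <- cumsum(c(TRUE, f_s[-1] != f_s[-length(f_s)]))
  gw <- as.numeric(tapply(w_s, grp, sum))
  gwy <- as.numeric(tapply(w_s * y_s, grp, sum))
  data.frame(pop_share = c(0, cumsum(gw) / sum(gw)),
             outcome_share = c(0, cumsum(gwy) / sum(gwy)))
}

## CI recovered from a concentration curve by trapezoid integration:
## CI = 1 - 2 * area under the curve. Used as a numerical cross-check.
ci_from_curve <- function(curve) {
  p <- curve$pop_share
  L <- curve$outcome_share
  area <- sum(diff(p) * (L[-1] + L[-length(L)]) / 2)
  1 - 2 * area
}
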