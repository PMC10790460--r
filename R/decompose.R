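#' Regression decomposition of a concentration index
#'
#' Attributes the Wagstaff concentration index of a binary outcome to the
#' covariates of its direct-unfairness logistic model, in the
#' Wagstaff–van Doorslaer–Watanabe style adapted to a nonlinear model. For
#' each model column k (a dummy level or a continuous covariate),
#' \deqn{contribution_k = \frac{m_k \bar{x}_k}{\mu} C_k}
#' where `m_k` is the average marginal effect of the covariate on the
#' outcome probability (each dummy switched 0 to 1 for every child, holding
#' the rest; the average derivative `mean(p(1-p)) * beta` for continuous
#' covariates), `x̄_k` its weighted mean and `C_k` its concentration index
#' against the same fractional rank used for the outcome's own index. The
#' residual is the part of the index the model's covariates do not explain;
#' shares are contributions as signed percentages of the index and sum to
#' exactly 100 with the residual. Negative shares are legal and reported
#' signed.
#'
#' When `|CI|` is below `tol` the percentage normalization is meaningless;
#' absolute contributions are returned with `share_percent = NA`.
#'
#' @param model a [fit_direct_unfairness_model()] fit.
#' @param y binary outcome used in the fit.
#' @param frank fractional ranks of the direct-unfairness index.
#' @param weights positive weights (the fit's weights).
#' @param tol threshold on `|CI|` below which shares are suppressed.
#' @return list of class `ci_decomposition`: `ci`, `terms` (per model
#'   column: term label, marginal effect, weighted mean, concentration
#'   index, elasticity, contribution, share_percent), `groups` (per-term
#'   aggregates from [aggregate_factor_groups()]), `residual` and
#'   `residual_percent`.
#' @export
decompose_ci <- function(model, y, frank, weights = NULL, tol = 1e-8) {
  stopifnot(inherits(model, "ranking_model"))
  fit <- model$glm
  w <- w_default(y, weights)
  check_weights(w, length(y))
  mu <- weighted_mean(y, w)
  if (mu <= 0) stop("decomposition undefined: mean coverage is zero", call. = FALSE)
  ci <- wagstaff_ci(y, frank, w)

  X <- stats::model.matrix(fit)
  beta <- stats::coef(fit)
  beta[is.na(beta)] <- 0
  eta <- as.numeric(X %*% beta)
  keep <- setdiff(colnames(X), "(Intercept)")
  assign_map <- attr(X, "assign")
  term_labels <- attr(stats::terms(fit), "term.labels")
  is_dummy <- vapply(keep, function(cn) all(X[, cn] %in% c(0, 1)), logical(1))

  rows <- lapply(keep, function(cn) {
    xk <- X[, cn]
    bk <- beta[[cn]]
    if (is_dummy[[cn]]) {
      ## switch the dummy 0 -> 1 for everyone, holding the rest
      p1 <- stats::plogis(eta - xk * bk + bk)
      p0 <- stats::plogis(eta - xk * bk)
      mk <- weighted_mean(p1 - p0, w)
    } else {
      mk <- weighted_mean(stats::plogis(eta) * (1 - stats::plogis(eta)), w) * bk
    }
    xbar <- weighted_mean(xk, w)
    ## C_k via the covariance form; the (2/xbar) factor cancels in the
    ## contribution, so a zero-mean column still contributes correctly
    cov_k <- weighted_cov(xk, frank, w)
    ck <- if (abs(xbar) > 0) 2 * cov_k / xbar else NA_real_
    contribution <- 2 * mk * cov_k / mu
    data.frame(column = cn,
               term = term_labels[assign_map[match(cn, colnames(X))]],
               marginal_effect = mk, mean = xbar, rank_ci = ck,
               elasticity = mk * xbar / mu, contribution = contribution,
               stringsAsFactors = FALSE)
  })
  terms_df <- do.call(rbind, rows)
  if (is.null(terms_df)) {  # intercept-only model
    terms_df <- data.frame(column = character(0), term = character(0),
                           marginal_effect = numeric(0), mean = numeric(0),
                           rank_ci = numeric(0), elasticity = numeric(0),
                           contribution = numeric(0))
  }
  residual <- ci - sum(terms_df$contribution)

  if (abs(ci) < tol) {
    terms_df$share_percent <- NA_real_
    residual_pct <- NA_real_
  } else {
    terms_df$share_percent <- 100 * terms_df$contribution / ci
    residual_pct <- 100 * residual / ci
  }

  structure(list(outcome = model$outcome, ci = ci, mu = mu,
                 terms = terms_df,
                 groups = aggregate_factor_groups(terms_df),
                 residual = residual, residual_percent = residual_pct),
            class = "ci_decomposition")
}

#' Aggregate dummy-level contributions into factor groups
#'
#' A categorical covariate enters the model as several dummy columns; its
#' reported share is the sum of its dummies' shares (e.g. the education
#' group aggregates every education level). Grouping defaults to the model
#' term each column came from; a custom named grouping (column -> group)
#' must cover every column.
#'
#' @param terms_df the `terms` data frame of a [decompose_ci()] result.
#' @param grouping optional named character vector mapping column names to
#'   group labels; default: the model term of each column.
#' @return data frame with one row per group: summed contribution and share.
#' @export
aggregate_factor_groups <- function(terms_df, grouping = NULL) {
  if (nrow(terms_df) == 0) {
    return(data.frame(group = character(0), contribution = numeric(0),
                      share_percent = numeric(0)))
  }
  if (is.null(grouping)) {
    grp <- terms_df$term
  } else {
    unassigned <- setdiff(terms_df$column, names(grouping))
    if (length(unassigned) > 0) {
      stop("unassigned dummy column(s): ", paste(unassigned, collapse = ", "),
           call. = FALSE)
    }
    grp <- unname(grouping[terms_df$column])
  }
  out <- data.frame(group = unique(grp), stringsAsFactors = FALSE)
  out$contribution <- vapply(out$group, function(g)
    sum(terms_df$contribution[grp == g]), numeric(1))
  if ("share_percent" %in% names(terms_df)) {
    out$share_percent <- vapply(out$group, function(g)
      sum(terms_df$share_percent[grp == g]), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' @export
print.ci_decomposition <- function(x, digits = 3, ...) {
  cat("Decomposition of the concentration index for '", x$outcome, "'\n", sep = "")
  cat("  CI =", round(x$ci, digits), " (mean coverage", round(x$mu, digits), ")\n")
  g <- x$groups
  if (nrow(g) > 0) {
    g$contribution <- round(g$contribution, digits)
    if (!is.null(g$share_percent)) g$share_percent <- round(g$share_percent, 1)
    print(g, row.names = FALSE)
  }
  cat("  residual:", round(x$residual, digits))
  if (!is.na(x$residual_percent)) {
    cat(sprintf(" (%.1f%% unexplained)", x$residual_percent))
  }
  cat("\n")
  invisible(x)
}
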