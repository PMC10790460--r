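#' Specify fair and unfair sources of variation
#'
#' Declares which covariates are treated as fair (legitimate) and unfair
#' (illegitimate) sources of variation in vaccination coverage, and the
#' "more privileged" level of each unfair covariate. Fair variation is the
#' child's age: children too young to be due a dose are not expected to be
#' vaccinated. Unfair variation covers region of residence, urban/rural
#' setting, maternal education, household socioeconomic status, the child's
#' sex and insurance coverage. The privileged level of each unfair covariate
#' is used as the regression reference level, so fitted log-odds measure
#' disadvantage relative to the most privileged situation.
#'
#' @param fair character vector of fair covariate names. The per-outcome
#'   underage indicator is always added when available (see
#'   [vaccine_equity()]); `"age_months"` enters continuously by default.
#' @param unfair character vector of unfair covariate names.
#' @param privileged named list/character giving, for each unfair covariate,
#'   its most privileged category.
#' @return An object of class `fairness_spec`.
#' @examples
#' fairness_spec()
#' fairness_spec(unfair = c("region", "residence"),
#'               privileged = list(region = "Central", residence = "urban"))
#' @export
fairness_spec <- function(fair = "age_months",
                          unfair = c("region", "residence", "maternal_education",
                                     "ses_quintile", "sex", "insured"),
                          privileged = list(region = NULL,
                                            residence = "urban",
                                            maternal_education = NULL,
                                            ses_quintile = "5",
                                            sex = "male",
                                            insured = "yes")) {
  fair <- as.character(fair)
  unfair <- as.character(unfair)
  if (length(intersect(fair, unfair)) > 0) {
    stop("fair and unfair covariate sets overlap: ",
         paste(intersect(fair, unfair), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(privileged), unfair)
  if (length(extra) > 0) {
    stop("privileged levels declared for covariates not listed as unfair: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  structure(list(fair = fair, unfair = unfair, privileged = privileged),
            class = "fairness_spec")
}

#' @export
print.fairness_spec <- function(x, ...) {
  cat("Fairness specification\n")
  cat("  fair:  ", paste(x$fair, collapse = ", "), "\n")
  cat("  unfair:", paste(x$unfair, collapse = ", "), "\n")
  pl <- vapply(x$unfair, function(v) {
    p <- x$privileged[[v]]
    if (is.null(p)) "(first level)" else as.character(p)
  }, character(1))
  cat("  privileged levels:\n")
  for (v in x$unfair) cat("    ", v, "= ", pl[[v]], "\n")
  invisible(x)
}

## Relevel every unfair factor so its privileged category is the reference.
## NULL privileged level keeps the natural first level.
apply_privileged_reference <- function(data, spec) {
  for (v in spec$unfair) {
    if (!v %in% names(data)) next
    f <- data[[v]]
    if (!is.factor(f)) f <- factor(f)
    p <- spec$privileged[[v]]
    if (!is.null(p)) {
      p <- as.character(p)
      if (!p %in% levels(f)) {
        stop("privileged level '", p, "' not found in covariate '", v, "'",
             call. = FALSE)
      }
      f <- stats::relevel(f, ref = p)
    }
    data[[v]] <- f
  }
  data
}

#' Fit the direct-unfairness logistic model for one outcome
#'
#' Maximum-likelihood logistic regression of a binary vaccination outcome on
#' the fair and unfair covariates of a [fairness_spec()]. The fitted
#' probabilities are the direct-unfairness index: the coverage a child is
#' predicted to attain given only their fair and unfair circumstances.
#' Categorical covariates are dummy-encoded against the declared privileged
#' reference levels; survey weights enter as frequency-style weights.
#'
#' Covariates that are constant in the data (a single observed level) are
#' dropped with a message rather than an error, since subsetting (e.g. to
#' under-24-month children) can collapse a level.
#'
#' @param y binary outcome vector (0/1), both classes present.
#' @param data data frame of covariates (one row per child).
#' @param spec a [fairness_spec()].
#' @param weights positive survey weights, default all 1.
#' @param outcome_name label stored for reporting.
#' @return An object of class `ranking_model`: the underlying `glm` fit plus
#'   the covariates used, reference levels and convergence flag.
#' @export
fit_direct_unfairness_model <- function(y, data, spec = fairness_spec(),
                                        weights = NULL, outcome_name = "outcome") {
  n <- length(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  w <- w_default(y, weights)
  check_weights(w, n)
  if (length(unique(y)) < 2) {
    stop("degenerate outcome: '", outcome_name, "' takes a single value (",
         y[1], ")", call. = FALSE)
  }

  covs <- c(spec$fair, spec$unfair)
  missing_covs <- setdiff(covs, names(data))
  missing_covs <- setdiff(missing_covs, "underage")  # supplied by caller when defined
  if (length(missing_covs) > 0) {
    stop("covariates absent from data: ", paste(missing_covs, collapse = ", "),
         call. = FALSE)
  }
  covs <- intersect(covs, names(data))
  data <- apply_privileged_reference(data, spec)

  ## drop covariates with no variation in this (possibly subset) sample
  keep <- vapply(covs, function(v) length(unique(data[[v]])) > 1, logical(1))
  if (any(!keep)) {
    message("dropping constant covariate(s): ", paste(covs[!keep], collapse = ", "))
  }
  covs <- covs[keep]
  if (length(covs) == 0) {
    form <- stats::as.formula(".y ~ 1")
  } else {
    form <- stats::as.formula(paste(".y ~", paste(covs, collapse = " + ")))
  }

  df <- data[, covs, drop = FALSE]
  df$.y <- y
  df$.w <- w

  ## maxit raised well past the default: the underage indicator's structural
  ## zeros make its coefficient saturate slowly before the deviance settles
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = df, weights = .w,
               control = stats::glm.control(maxit = 100)),
    warning = function(cnd) {
      if (grepl("non-integer #successes", conditionMessage(cnd))) {
        invokeRestart("muffleWarning")
      }
    }
  )

  ## Separation guard. The underage indicator separates structurally (a child
  ## cannot have received a dose that is not yet due) — that is the fair
  ## covariate doing its job, so it is exempt; any other covariate driving
  ## fitted probabilities to 0/1 is reported as separation.
  p <- stats::fitted(fit)
  if (any(p < 1e-8) || any(p > 1 - 1e-8)) {
    b <- stats::coef(fit)
    bad <- names(b)[!is.na(b) & abs(b) > 10 & names(b) != "(Intercept)" &
                      !grepl("^underage", names(b))]
    if (length(bad) > 0) {
      stop("perfect or quasi-perfect separation in outcome '", outcome_name,
           "'; suspect covariate level(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }

  structure(list(outcome = outcome_name,
                 glm = fit,
                 covariates = covs,
                 reference_levels = lapply(df[covs], function(x)
                   if (is.factor(x)) levels(x)[1] else NA_character_),
                 converged = fit$converged,
                 n = n),
            class = "ranking_model")
}

#' @export
print.ranking_model <- function(x, ...) {
  cat("Direct-unfairness logistic model for outcome '", x$outcome, "'\n", sep = "")
  cat("  n =", x$n, "| converged:", x$converged, "\n")
  cat("  coefficients (log-odds):\n")
  print(round(stats::coef(x$glm), 4))
  invisible(x)
}

#' @export
coef.ranking_model <- function(object, ...) stats::coef(object$glm)

#' Predict the direct-unfairness index
#'
#' Per-child predicted coverage probability from a fitted [ranking_model].
#' Unseen factor levels in `newdata` are an error (the model cannot place
#' them relative to the privileged reference).
#'
#' @param model a `ranking_model`.
#' @param newdata data frame of covariates; default: the fitting data.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_unfairness_index <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "ranking_model"))
  if (is.null(newdata)) return(as.numeric(stats::fitted(model$glm)))
  newdata <- as.data.frame(newdata)
  for (v in model$covariates) {
    if (!v %in% names(newdata)) {
      stop("covariate '", v, "' missing from newdata", call. = FALSE)
    }
    tr <- model$glm$model[[v]]
    if (is.factor(tr)) {
      unseen <- setdiff(unique(as.character(newdata[[v]])), levels(tr))
      if (length(unseen) > 0) {
        stop("unseen level(s) in covariate '", v, "': ",
             paste(unseen, collapse = ", "), call. = FALSE)
      }
      newdata[[v]] <- factor(newdata[[v]], levels = levels(tr))
    }
  }
  as.numeric(stats::predict(model$glm, newdata = newdata, type = "response"))
}

#' Weighted fractional (midpoint CDF) rank
#'
#' Position of each observation in the weighted cumulative distribution of a
#' ranking variable: after sorting ascending, observation i gets
#' F_i = (cumulative weight before i + w_i / 2) / total weight. All members of
#' a tie group receive the group's weighted midpoint rank. By construction the
#' weighted mean of the ranks is exactly 0.5 and ranks lie strictly inside
#' (0, 1).
#'
#' @param values numeric ranking variable (higher = more privileged).
#' @param weights positive weights, default all 1.
#' @return numeric vector of fractional ranks, in the input order.
#' @examples
#' fractional_rank(c(3, 1, 2))          # 0.8333, 0.1667, 0.5
#' fractional_rank(c(1, 2), c(1, 3))    # 0.125, 0.625
#' @export
fractional_rank <- function(values, weights = NULL) {
  n <- length(values)
  if (n == 0) stop("empty input to fractional_rank", call. = FALSE)
  if (anyNA(values)) stop("missing values in ranking variable", call. = FALSE)
  w <- w_default(values, weights)
  check_weights(w, n)
  total <- sum(w)

  ## weighted midpoint rank per tie group of the sorted values
  ord <- order(values)
  v_s <- values[ord]
  w_s <- w[ord]
  grp <- cumsum(c(TRUE, v_s[-1] != v_s[-n]))   # tie-group ids along sorted order
  gw <- tapply(w_s, grp, sum)                  # group total weights
  cum_before <- cumsum(c(0, gw[-length(gw)]))
  f_group <- (cum_before + gw / 2) / total
  f_sorted <- f_group[grp]
  out <- numeric(n)
  out[ord] <- f_sorted
  out
}

#' Rank quintile from fractional ranks
#'
#' Assigns quintile 1 (bottom 20% of cumulative weight) through 5 (top 20%)
#' by cutting the fractional rank at 0.2/0.4/0.6/0.8. Tied values share a
#' fractional rank, hence a quintile.
#'
#' @param frank fractional ranks from [fractional_rank()].
#' @return integer vector in 1..5.
#' @export
rank_quintile <- function(frank) {
  q <- pmin(floor(frank * 5) + 1L, 5L)
  as.integer(q)
}
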