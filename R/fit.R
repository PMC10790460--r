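#' Fit a composite vaccine-equity assessment for one outcome
#'
#' The core estimator of the package. For a binary vaccination outcome
#' (a single dose, `ZERO`, `FULL` or `COMPLETE`), children are ranked
#' by a direct-unfairness index — the predicted coverage from a logistic
#' model of fair (age, underage-for-dose) and unfair (region, residence,
#' maternal education, socioeconomic status, sex, insurance) sources of
#' variation — and the ranking's fractional rank enters a battery of equity
#' metrics:
#' \itemize{
#'   \item mean weighted coverage `mu`;
#'   \item the Wagstaff concentration index `2/mu * Cov(y, F)` and its
#'     Erreygers correction `4 * mu * CI_W`, with confidence bounds;
#'   \item the absolute equity gap (top minus bottom rank quintile
#'     coverage) with its bounds;
#'   \item the equity level `1 - |CI_W|`;
#'   \item a regression decomposition of the index into signed factor
#'     shares plus an unexplained residual.
#' }
#' With `ranking = "wealth"` the fractional rank is taken on the
#' socioeconomic score alone (wealth-only concentration index, comparable
#' to conventional pro-rich/pro-poor indices) and no model is fitted.
#'
#' `FULL` is assessed on children under 24 months, `COMPLETE` on children
#' of 24 months and over; other outcomes use all children.
#'
#' @param outcome outcome name: a schedule dose label, `"ZERO"`, `"FULL"`
#'   or `"COMPLETE"`.
#' @param data population table (see [simulate_population()] or
#'   [read_population()]): covariates, `weight`, dose receipt columns, and
#'   either `ses_score`/`ses_quintile` or `asset_*` columns from which the
#'   wealth index is built.
#' @param schedule an [epi_schedule()].
#' @param spec a [fairness_spec()].
#' @param ranking `"composite"` (default) or `"wealth"`.
#' @param outcomes optional precomputed [derive_outcomes()] table aligned
#'   with `data`; derived internally when absent.
#' @param conf_mode bound mode for [ci_confidence_bounds()].
#' @param zero_dose_rule passed to [derive_outcomes()].
#' @param decompose fit and store the factor decomposition (composite
#'   ranking only).
#' @return An object of class `vaccine_equity` with components `mu`,
#'   `ci_wagstaff`, `ci_erreygers`, `aeg`, `ci_bounds`, `aeg_bounds`,
#'   `equity_level`, `quintile_summary`, `model` (composite only), `vci_du`,
#'   `frank`, `rank_quintile`, `decomposition` and bookkeeping fields.
#'   Methods: [print.vaccine_equity()], [summary.vaccine_equity()], `coef`,
#'   `predict`, `plot` (concentration curve), `residuals`, `simulate`.
#' @examples
#' cfg <- sim_config(n_children = 400,
#'                   effects = list(DPT3 = list(intercept = 0,
#'                                              residence = c(urban = 1.4))))
#' pop <- simulate_population(cfg, seed = 7)
#' fit <- vaccine_equity("DPT3", pop)
#' fit
#' @export
vaccine_equity <- function(outcome, data,
                           schedule = epi_schedule(),
                           spec = fairness_spec(),
                           ranking = c("composite", "wealth"),
                           outcomes = NULL,
                           conf_mode = c("estimator", "as_printed"),
                           zero_dose_rule = c("any_age", "strict"),
                           decompose = TRUE) {
  ranking <- match.arg(ranking)
  conf_mode <- match.arg(conf_mode)
  zero_dose_rule <- match.arg(zero_dose_rule)
  cl <- match.call()
  data <- as.data.frame(data)

  if (is.null(outcomes)) {
    outcomes <- derive_outcomes(data, schedule, zero_dose_rule = zero_dose_rule)
  }
  if (!outcome %in% names(outcomes)) {
    stop("unknown outcome '", outcome, "'; available: ",
         paste(setdiff(names(outcomes),
                       grep("^underage_", names(outcomes), value = TRUE)),
               collapse = ", "), call. = FALSE)
  }

  data <- ensure_ses(data, spec)
  y_all <- outcomes[[outcome]]
  sel <- !is.na(y_all)              # FULL/COMPLETE age windows leave NAs
  y <- y_all[sel]
  dat <- data[sel, , drop = FALSE]
  w <- if ("weight" %in% names(dat)) dat$weight else rep(1, nrow(dat))
  check_weights(w, length(y))

  ucol <- underage_column(outcome)
  if (!is.null(ucol) && ucol %in% names(outcomes)) {
    dat$underage <- outcomes[[ucol]][sel]
  }

  if (ranking == "composite") {
    sp <- spec
    if (!is.null(ucol) && "underage" %in% names(dat) &&
        !"underage" %in% sp$fair) {
      sp$fair <- c(sp$fair, "underage")
    }
    model <- fit_direct_unfairness_model(y, dat, sp, weights = w,
                                         outcome_name = outcome)
    vci_du <- predict_unfairness_index(model)
  } else {
    model <- NULL
    ## survey-provided wealth quintiles (no asset battery) rank coarsely but
    ## validly: all children in a quintile tie at its midpoint rank
    vci_du <- dat$ses_score %||% as.numeric(dat$ses_quintile)
    if (is.null(vci_du)) {
      stop("wealth ranking needs 'ses_score', 'ses_quintile' or asset columns",
           call. = FALSE)
    }
  }

  frank <- fractional_rank(vci_du, w)
  mu <- weighted_mean(y, w)
  ci_w <- wagstaff_ci(y, frank, w)
  ci_e <- erreygers_ci(mu, ci_w)
  gap <- absolute_equity_gap(y, frank, w)

  dec <- NULL
  if (decompose && ranking == "composite") {
    dec <- decompose_ci(model, y, frank, w)
  }

  structure(list(call = cl, outcome = outcome, ranking = ranking,
                 n = length(y), n_total = length(y_all),
                 mu = mu, ci_wagstaff = ci_w, ci_erreygers = ci_e,
                 aeg = gap$aeg,
                 ci_bounds = ci_confidence_bounds(ci_w, y, w, mode = conf_mode),
                 aeg_bounds = aeg_confidence_bounds(gap$aeg, gap$quintile_summary),
                 equity_level = equity_level(ci_w),
                 quintile_summary = gap$quintile_summary,
                 model = model, vci_du = vci_du, frank = frank,
                 rank_quintile = rank_quintile(frank),
                 decomposition = dec, y = y, weights = w,
                 conf_mode = conf_mode),
            class = "vaccine_equity")
}

#' Attach the asset-based wealth index to a population table
#'
#' Builds [wealth_scores()] from the table's `asset_*` columns and adds
#' `ses_score` and `ses_quintile` (kept untouched when already present, as
#' when survey-provided wealth quintiles are ingested directly through the
#' column mapping). Called automatically by [vaccine_equity()].
#'
#' @param data population table.
#' @return the table with `ses_score` and `ses_quintile` columns.
#' @export
add_wealth_index <- function(data) {
  have_score <- "ses_score" %in% names(data)
  have_quintile <- "ses_quintile" %in% names(data)
  asset_cols <- grep("^asset_", names(data), value = TRUE)
  if ((!have_score || !have_quintile) && length(asset_cols) >= 1) {
    w <- if ("weight" %in% names(data)) data$weight else NULL
    wr <- wealth_scores(data[, asset_cols, drop = FALSE], weights = w)
    if (!have_score) data$ses_score <- wr$ses_score
    if (!have_quintile) data$ses_quintile <- wr$ses_quintile
  }
  if ("ses_quintile" %in% names(data) && !is.factor(data$ses_quintile)) {
    data$ses_quintile <- factor(data$ses_quintile, levels = sort(unique(data$ses_quintile)))
  }
  data
}

ensure_ses <- function(data, spec) add_wealth_index(data)

#' @export
print.vaccine_equity <- function(x, digits = 3, ...) {
  cat("Vaccine equity assessment —", x$outcome,
      sprintf("(%s ranking, n = %d)\n", x$ranking, x$n))
  cat(sprintf("  coverage            %.1f%%\n", 100 * x$mu))
  cat(sprintf("  Wagstaff CI         %.*f  (%.*f, %.*f)\n", digits,
              x$ci_wagstaff, digits, x$ci_bounds[1], digits, x$ci_bounds[2]))
  cat(sprintf("  Erreygers CI        %.*f\n", digits, x$ci_erreygers))
  cat(sprintf("  absolute equity gap %.*f  (%.*f, %.*f)\n", digits, x$aeg,
              digits, x$aeg_bounds[1], digits, x$aeg_bounds[2]))
  cat(sprintf("  equity level        %.2f\n", x$equity_level))
  invisible(x)
}

#' Summarize a vaccine-equity fit
#'
#' @param object a [vaccine_equity()] fit.
#' @param ... unused.
#' @return list of class `summary.vaccine_equity` with the metric row,
#'   quintile coverage table and decomposition group shares.
#' @export
summary.vaccine_equity <- function(object, ...) {
  metrics <- data.frame(outcome = object$outcome, ranking = object$ranking,
                        n = object$n, coverage = object$mu,
                        ci_wagstaff = object$ci_wagstaff,
                        ci_low = object$ci_bounds[1],
                        ci_high = object$ci_bounds[2],
                        ci_erreygers = object$ci_erreygers,
                        aeg = object$aeg,
                        aeg_low = object$aeg_bounds[1],
                        aeg_high = object$aeg_bounds[2],
                        equity_level = object$equity_level)
  structure(list(metrics = metrics,
                 quintile_summary = object$quintile_summary,
                 decomposition = if (!is.null(object$decomposition))
                   object$decomposition$groups,
                 residual_percent = if (!is.null(object$decomposition))
                   object$decomposition$residual_percent),
            class = "summary.vaccine_equity")
}

#' @export
print.summary.vaccine_equity <- function(x, ...) {
  m <- x$metrics
  cat("Vaccine equity assessment —", m$outcome,
      sprintf("(%s ranking, n = %d)\n\n", m$ranking, m$n))
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], function(v) round(v, 3))
  print(m, row.names = FALSE)
  cat("\nCoverage by rank quintile (1 = most disadvantaged):\n")
  qs <- x$quintile_summary
  qs$coverage <- round(qs$coverage, 3)
  qs$s2 <- round(qs$s2, 4)
  qs$n_eff <- round(qs$n_eff, 1)
  print(qs[, c("quintile", "n", "n_eff", "coverage", "s2")], row.names = FALSE)
  if (!is.null(x$decomposition)) {
    cat("\nFactor shares of the concentration index (%):\n")
    g <- x$decomposition
    g$contribution <- round(g$contribution, 4)
    if (!is.null(g$share_percent)) g$share_percent <- round(g$share_percent, 1)
    print(g, row.names = FALSE)
    if (!is.na(x$residual_percent)) {
      cat(sprintf("  unexplained residual: %.1f%%\n", x$residual_percent))
    }
  }
  invisible(x)
}

#' @export
coef.vaccine_equity <- function(object, ...) {
  if (is.null(object$model)) {
    stop("wealth-only ranking has no fitted model coefficients", call. = FALSE)
  }
  stats::coef(object$model$glm)
}

#' @export
predict.vaccine_equity <- function(object, newdata = NULL, ...) {
  if (is.null(object$model)) {
    stop("wealth-only ranking has no model to predict from", call. = FALSE)
  }
  predict_unfairness_index(object$model, newdata)
}

#' @export
residuals.vaccine_equity <- function(object, ...) {
  object$y - object$vci_du
}

#' Plot the concentration curve of a fit
#'
#' Cumulative outcome share against cumulative population share (children
#' ordered from most disadvantaged to most privileged), with the 45-degree
#' line of perfect equality. A curve bowed below the diagonal means coverage
#' is concentrated among the privileged.
#'
#' @param x a [vaccine_equity()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vaccine_equity <- function(x, ...) {
  cc <- concentration_curve(x$y, x$frank, x$weights)
  graphics::plot(cc$pop_share, cc$outcome_share, type = "l", lwd = 2,
                 xlab = "cumulative population share (disadvantaged first)",
                 ylab = "cumulative outcome share",
                 main = sprintf("%s: CI = %.3f", x$outcome, x$ci_wagstaff), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(cc)
}

#' @export
simulate.vaccine_equity <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$model)) {
    stop("wealth-only ranking has no model to simulate from", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- object$vci_du
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
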