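#' Equity metrics for a set of outcomes and ranking kinds
#'
#' Runs [vaccine_equity()] for every requested outcome under each ranking
#' kind and stacks the metric rows into one national-level report table
#' (coverage, Wagstaff and Erreygers indices, absolute equity gap, bounds,
#' equity level — one row per outcome x ranking).
#'
#' @param data population table.
#' @param outcomes character vector of outcome names; default: every
#'   schedule dose plus `ZERO`, `FULL` and `COMPLETE`.
#' @param ranking character subset of `c("composite", "wealth")`.
#' @param schedule an [epi_schedule()].
#' @param spec a [fairness_spec()].
#' @param ... further arguments to [vaccine_equity()].
#' @return list with `metrics` (the stacked table) and `fits` (the named
#'   list of `vaccine_equity` objects, keyed `outcome.ranking`).
#' @export
compute_equity_suite <- function(data, outcomes = NULL,
                                 ranking = c("composite", "wealth"),
                                 schedule = epi_schedule(),
                                 spec = fairness_spec(), ...) {
  ranking <- match.arg(ranking, several.ok = TRUE)
  if (is.null(outcomes)) outcomes <- c(schedule$dose, "ZERO", "FULL", "COMPLETE")
  derived <- derive_outcomes(data, schedule)
  fits <- list()
  rows <- list()
  for (out in outcomes) {
    for (rk in ranking) {
      fit <- vaccine_equity(out, data, schedule = schedule, spec = spec,
                            ranking = rk, outcomes = derived, ...)
      key <- paste(out, rk, sep = ".")
      fits[[key]] <- fit
      rows[[key]] <- summary(fit)$metrics
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(metrics = metrics, fits = fits)
}

#' Weighted coverage by sociodemographic stratum
#'
#' Per-outcome weighted coverage within each level of the given covariates
#' (the sociodemographic coverage table of a survey report).
#'
#' @param data population table.
#' @param outcome_table a [derive_outcomes()] table aligned with `data`.
#' @param outcomes outcome names to tabulate.
#' @param by covariate names to stratify on.
#' @return long data frame: covariate, level, outcome, n, coverage.
#' @export
stratum_coverage <- function(data, outcome_table, outcomes,
                             by = c("region", "residence",
                                    "maternal_education", "sex", "insured")) {
  by <- intersect(by, names(data))
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  rows <- list()
  for (v in by) {
    for (lev in unique(as.character(data[[v]]))) {
      idx <- as.character(data[[v]]) == lev
      for (out in outcomes) {
        y <- outcome_table[[out]][idx]
        keep <- !is.na(y)
        rows[[length(rows) + 1]] <- data.frame(
          covariate = v, level = lev, outcome = out, n = sum(keep),
          coverage = if (any(keep)) weighted_mean(y[keep], w[idx][keep])
                     else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
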