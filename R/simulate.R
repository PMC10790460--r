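#' Configuration for the synthetic survey generator
#'
#' Describes a DHS-like child-level population with known, planted inequity:
#' categorical covariate strata (region, urban/rural residence, maternal
#' education, insurance, sex), ages in months 0-59, an asset battery loading
#' on a latent socioeconomic factor, survey weights, and per-dose log-odds
#' effects that determine dose receipt through a logistic model. Because the
#' data-generating effects are declared, downstream estimators can be
#' checked against analytic truth (see [expected_stratum_coverage()]).
#'
#' @param n_children number of children (>= 1).
#' @param region_levels named probability vector over region labels.
#' @param urban_prob probability of urban residence.
#' @param education_levels named probability vector over ordered maternal
#'   education labels (least to most educated).
#' @param insurance_prob probability of health-insurance coverage.
#' @param sex_prob probability the child is male.
#' @param age_dist probability vector over ages 0..59 months (default
#'   uniform).
#' @param n_assets number of binary asset indicators.
#' @param asset_loadings log-odds loading of each asset on the latent
#'   standard-normal SES factor (recycled to `n_assets`).
#' @param asset_intercepts baseline log-odds of owning each asset (recycled).
#' @param effects named list, one element per dose label, each a list with
#'   `intercept` (log-odds) and optionally named vectors per covariate
#'   (`region`, `residence`, `maternal_education`, `sex`, `insured`) whose
#'   entries add log-odds for specific levels, plus scalar `ses` multiplying
#'   the latent SES factor. Doses without an entry default to the
#'   `default_effect`. Only doses due at the child's age can be received.
#' @param default_effect effect list applied to doses absent from `effects`.
#' @param weight_model `list(kind = "constant")` (all weights 1, default) or
#'   `list(kind = "lognormal", meanlog =, sdlog =)` to stress weighted
#'   estimators.
#' @param monotone if `TRUE`, within each multi-dose antigen series dose k
#'   requires dose k-1 (drop-out pattern); default independent receipts.
#' @param missing_rate probability a due dose's record is missing at random.
#' @param schedule an [epi_schedule()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_children = 1000,
                       region_levels = c(Central = 0.3, Eastern = 0.25,
                                         Northern = 0.2, Western = 0.25),
                       urban_prob = 0.25,
                       education_levels = c(none = 0.2, primary = 0.5,
                                            secondary = 0.2, higher = 0.1),
                       insurance_prob = 0.05,
                       sex_prob = 0.5,
                       age_dist = NULL,
                       n_assets = 10,
                       asset_loadings = 1.5,
                       asset_intercepts = 0,
                       effects = list(),
                       default_effect = list(intercept = 1.0),
                       weight_model = list(kind = "constant"),
                       monotone = FALSE,
                       missing_rate = 0,
                       schedule = epi_schedule()) {
  cfg <- list(n_children = n_children, region_levels = region_levels,
              urban_prob = urban_prob, education_levels = education_levels,
              insurance_prob = insurance_prob, sex_prob = sex_prob,
              age_dist = age_dist %||% rep(1 / 60, 60),
              n_assets = n_assets,
              asset_loadings = rep_len(asset_loadings, n_assets),
              asset_intercepts = rep_len(asset_intercepts, n_assets),
              effects = effects, default_effect = default_effect,
              weight_model = weight_model, monotone = monotone,
              missing_rate = missing_rate, schedule = schedule)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_prob <- function(p, field) {
    if (length(p) == 0 || anyNA(p) || any(p < 0 | p > 1)) {
      stop("configuration error in '", field, "': probabilities must lie in [0, 1]",
           call. = FALSE)
    }
  }
  check_cat <- function(p, field) {
    if (length(p) == 0 || is.null(names(p)) || any(!nzchar(names(p)))) {
      stop("configuration error in '", field, "': need a non-empty named vector",
           call. = FALSE)
    }
    check_prob(p, field)
    if (abs(sum(p) - 1) > 1e-8) {
      stop("configuration error in '", field, "': category probabilities must sum to 1",
           call. = FALSE)
    }
  }
  if (!is.numeric(cfg$n_children) || cfg$n_children < 1) {
    stop("configuration error in 'n_children': need at least 1 child", call. = FALSE)
  }
  check_cat(cfg$region_levels, "region_levels")
  check_cat(cfg$education_levels, "education_levels")
  for (f in c("urban_prob", "insurance_prob", "sex_prob", "missing_rate")) {
    check_prob(cfg[[f]], f)
  }
  if (length(cfg$age_dist) != 60 || abs(sum(cfg$age_dist) - 1) > 1e-8) {
    stop("configuration error in 'age_dist': need 60 probabilities (ages 0-59) summing to 1",
         call. = FALSE)
  }
  if (!cfg$weight_model$kind %in% c("constant", "lognormal")) {
    stop("configuration error in 'weight_model': kind must be constant or lognormal",
         call. = FALSE)
  }
  known <- cfg$schedule$dose
  unknown <- setdiff(names(cfg$effects), known)
  if (length(unknown) > 0) {
    stop("configuration error in 'effects': unknown dose(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

## linear predictor of one dose's receipt model for given covariate rows
dose_linear_predictor <- function(eff, cov) {
  lp <- rep(eff$intercept %||% 0, nrow(cov))
  for (v in c("region", "residence", "maternal_education", "sex", "insured")) {
    ev <- eff[[v]]
    if (is.null(ev)) next
    lev <- as.character(cov[[v]])
    hit <- lev %in% names(ev)
    lp[hit] <- lp[hit] + ev[lev[hit]]
  }
  if (!is.null(eff$ses)) lp <- lp + eff$ses * cov$ses_latent
  lp
}

#' Generate a synthetic survey population
#'
#' Draws `n_children` child records from a [sim_config()]: covariates from
#' their declared distributions, a latent standard-normal SES factor with
#' Bernoulli asset indicators loading on it, survey weights, and per-dose
#' receipts Bernoulli(logistic(linear predictor)) — but only for doses
#' already due at the child's age in months; not-yet-due doses are 0.
#' Identical config and seed reproduce the identical table.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the generator is fully reproducible given
#'   (config, seed).
#' @return data frame: `child_id`, `age_months`, `sex`, `region`,
#'   `residence`, `maternal_education`, `insured`, `weight`, `ses_latent`,
#'   `asset_*` columns, and one 0/1 (or NA under missingness) column per
#'   schedule dose.
#' @export
simulate_population <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  n <- as.integer(config$n_children)
  set.seed(as.integer(seed))

  pop <- data.frame(
    child_id = seq_len(n),
    age_months = sample(0:59, n, replace = TRUE, prob = config$age_dist),
    sex = sample(c("male", "female"), n, replace = TRUE,
                 prob = c(config$sex_prob, 1 - config$sex_prob)),
    region = sample(names(config$region_levels), n, replace = TRUE,
                    prob = config$region_levels),
    residence = sample(c("urban", "rural"), n, replace = TRUE,
                       prob = c(config$urban_prob, 1 - config$urban_prob)),
    maternal_education = sample(names(config$education_levels), n,
                                replace = TRUE, prob = config$education_levels),
    insured = sample(c("yes", "no"), n, replace = TRUE,
                     prob = c(config$insurance_prob, 1 - config$insurance_prob)),
    stringsAsFactors = FALSE
  )
  pop$maternal_education <- factor(pop$maternal_education,
                                   levels = names(config$education_levels),
                                   ordered = FALSE)

  pop$weight <- switch(config$weight_model$kind,
    constant = rep(1, n),
    lognormal = stats::rlnorm(n, config$weight_model$meanlog %||% 0,
                              config$weight_model$sdlog %||% 0.5))

  pop$ses_latent <- stats::rnorm(n)
  if (config$n_assets > 0) {
    for (j in seq_len(config$n_assets)) {
      p <- stats::plogis(config$asset_intercepts[j] +
                         config$asset_loadings[j] * pop$ses_latent)
      pop[[paste0("asset_", j)]] <- stats::rbinom(n, 1, p)
    }
  }

  sch <- config$schedule
  for (d in sch$dose) {
    eff <- config$effects[[d]] %||% config$default_effect
    p <- stats::plogis(dose_linear_predictor(eff, pop))
    due <- pop$age_months >= sch$due_age_months[sch$dose == d]
    rec <- integer(n)
    rec[due] <- stats::rbinom(sum(due), 1, p[due])
    pop[[d]] <- rec
  }

  if (config$monotone) {
    for (a in unique(sch$antigen)) {
      series <- sch$dose[sch$antigen == a][order(sch$dose_number[sch$antigen == a])]
      if (length(series) < 2) next
      for (k in 2:length(series)) {
        pop[[series[k]]] <- pop[[series[k]]] * pop[[series[k - 1]]]
      }
    }
  }

  if (config$missing_rate > 0) {
    for (d in sch$dose) {
      due <- pop$age_months >= sch$due_age_months[sch$dose == d]
      miss <- due & stats::runif(n) < config$missing_rate
      pop[[d]][miss] <- NA_integer_
    }
  }

  pop
}

#' Analytic stratum coverage for a configured dose
#'
#' The exact logistic-transform receipt probability of one dose in every
#' stratum of the categorical covariates its effect references, independent
#' of any seed — the oracle against which simulated stratum means are
#' checked. Probabilities are conditional on the dose being due at the
#' child's age. Only categorical effects admit finite strata; an `ses`
#' effect on the continuous latent factor is refused.
#'
#' @param config a [sim_config()].
#' @param antigen_dose dose label present in the schedule.
#' @return data frame with one column per referenced covariate plus `prob`;
#'   a single `(all)` row when the dose has an intercept-only effect.
#' @export
expected_stratum_coverage <- function(config, antigen_dose) {
  stopifnot(inherits(config, "sim_config"))
  if (!antigen_dose %in% config$schedule$dose) {
    stop("unknown antigen dose '", antigen_dose, "'", call. = FALSE)
  }
  eff <- config$effects[[antigen_dose]] %||% config$default_effect
  if (!is.null(eff$ses) && eff$ses != 0) {
    stop("analytic strata undefined: dose '", antigen_dose,
         "' has an effect on the continuous latent SES factor", call. = FALSE)
  }
  level_sets <- list(region = names(config$region_levels),
                     residence = c("urban", "rural"),
                     maternal_education = names(config$education_levels),
                     sex = c("male", "female"),
                     insured = c("yes", "no"))
  used <- intersect(names(level_sets), names(eff))
  if (length(used) == 0) {
    return(data.frame(stratum = "(all)",
                      prob = stats::plogis(eff$intercept %||% 0)))
  }
  grid <- expand.grid(level_sets[used], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$prob <- stats::plogis(dose_linear_predictor(eff, grid))
  grid
}
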