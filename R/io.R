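#' Column mapping for survey-style inputs
#'
#' Maps canonical field names (age_months, sex, region, residence,
#' maternal_education, insured, weight, ses_score/ses_quintile, asset and
#' dose columns) to the column names and codes of a source file. Each entry
#' is either a bare source column name (values used as-is) or a list
#' `list(col =, recode =, default =)` where `recode` is a named vector
#' mapping raw codes (as character) to canonical values and `default` is the
#' value assigned to codes absent from the map (omit it to make unlisted
#' codes an error).
#'
#' @param ... named mapping entries; dose mappings go under their dose
#'   labels (e.g. `DPT3 = list(col = "h7", recode = c("0" = 0, "1" = 1,
#'   "2" = 1, "3" = 1, "8" = NA))`).
#' @return list of class `column_mapping`.
#' @seealso [dhs_mapping_template()] for DHS child-recode variable names.
#' @export
column_mapping <- function(...) {
  entries <- list(...)
  if (length(entries) == 0 || is.null(names(entries)) ||
      any(!nzchar(names(entries)))) {
    stop("column_mapping needs named entries", call. = FALSE)
  }
  entries <- lapply(entries, function(e) {
    if (is.character(e) && length(e) == 1) e <- list(col = e)
    if (is.null(e$col)) stop("mapping entry lacks a source column", call. = FALSE)
    e
  })
  structure(entries, class = "column_mapping")
}

#' DHS child-recode mapping template
#'
#' A [column_mapping()] pre-filled with the standard DHS child-recode (KR
#' file) variable names for a CSV export: `b19`/`hw1` age in months, `b4`
#' sex, `v024` region, `v025` urban/rural, `v106` maternal education,
#' `v481` insurance, `v005` sampling weight (divided by 1e6 on read),
#' `v190` wealth quintile, and the `h*` immunization variables (h2 BCG,
#' h0 polio-0, h3/h5/h7 DPT 1-3, h4/h6/h8 polio 1-3, h54/h55/h56 PCV 1-3,
#' h9 measles). Dose codes 1 (card), 2 (recall) and 3 (card, date missing)
#' recode to received, 0 to not received, 8/9 (don't know / missing) to
#' missing. Ships as documentation of how a registered DHS export plugs into
#' the pipeline; adjust names to the survey wave at hand.
#'
#' @param age_col source column for age in months (`"hw1"` for older waves,
#'   `"b19"` for DHS-7).
#' @return a [column_mapping()].
#' @export
dhs_mapping_template <- function(age_col = "b19") {
  dose_recode <- c("0" = 0, "1" = 1, "2" = 1, "3" = 1,
                   "8" = NA, "9" = NA)
  dose <- function(col) list(col = col, recode = dose_recode, default = NA)
  column_mapping(
    age_months = age_col,
    sex = list(col = "b4", recode = c("1" = "male", "2" = "female")),
    region = "v024",
    residence = list(col = "v025", recode = c("1" = "urban", "2" = "rural")),
    maternal_education = list(col = "v106",
                              recode = c("0" = "none", "1" = "primary",
                                         "2" = "secondary", "3" = "higher")),
    insured = list(col = "v481", recode = c("0" = "no", "1" = "yes")),
    weight = list(col = "v005", transform = function(x) x / 1e6),
    ses_quintile = "v190",
    BCG = dose("h2"), OPV0 = dose("h0"),
    DPT1 = dose("h3"), DPT2 = dose("h5"), DPT3 = dose("h7"),
    OPV1 = dose("h4"), OPV2 = dose("h6"), OPV3 = dose("h8"),
    PCV1 = dose("h54"), PCV2 = dose("h55"), PCV3 = dose("h56"),
    MCV1 = dose("h9")
  )
}

#' Read a survey-style population table through a column mapping
#'
#' Reads a CSV and renames/recodes its columns to the canonical population
#' layout. Every mapped column must exist; raw codes not covered by a
#' recode map fall back to the entry's `default`, or raise an error naming
#' the code when no default is declared. A tally of recoded values per
#' field is attached as attribute `recode_log`.
#'
#' @param path CSV file path (or a data frame already in memory).
#' @param mapping a [column_mapping()].
#' @return canonical population data frame.
#' @export
read_population <- function(path, mapping) {
  stopifnot(inherits(mapping, "column_mapping"))
  raw <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  log <- list()
  for (field in names(mapping)) {
    e <- mapping[[field]]
    if (!e$col %in% names(raw)) {
      stop("mapped source column '", e$col, "' (field '", field,
           "') absent from input", call. = FALSE)
    }
    x <- raw[[e$col]]
    if (!is.null(e$transform)) x <- e$transform(x)
    if (!is.null(e$recode)) {
      key <- as.character(x)
      hit <- key %in% names(e$recode)
      if (any(!hit)) {
        if (!"default" %in% names(e)) {
          stop("unrecognized code(s) in field '", field, "': ",
               paste(unique(key[!hit]), collapse = ", "),
               " (no default declared)", call. = FALSE)
        }
      }
      val <- rep(if ("default" %in% names(e)) e$default else NA, length(x))
      val[hit] <- e$recode[key[hit]]
      log[[field]] <- table(raw = key, useNA = "ifany")
      x <- val
      ## numeric recode targets come back as named character; coerce
      if (all(is.na(x)) || suppressWarnings(!anyNA(as.numeric(x[!is.na(x)])))) {
        if (all(grepl("^-?[0-9.]+$", x[!is.na(x)]))) x <- as.numeric(x)
      }
      x <- unname(x)
    }
    out[[field]] <- x
  }
  attr(out, "recode_log") <- log
  out
}

#' Write / read a population table (round-trip safe CSV)
#'
#' @param pop population data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation or run configuration from a YAML file
#'
#' A YAML mirror of [sim_config()]'s arguments; named probability vectors
#' are given as mappings, the `effects` block as nested mappings keyed by
#' dose label.
#'
#' @param path YAML file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("region_levels", "education_levels")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$effects)) {
    raw$effects <- lapply(raw$effects, function(e) {
      lapply(e, function(v) if (is.list(v)) unlist(v) else v)
    })
  }
  if (!is.null(raw$default_effect)) {
    raw$default_effect <- lapply(raw$default_effect,
                                 function(v) if (is.list(v)) unlist(v) else v)
  }
  do.call(sim_config, raw)
}

#' Run the full equity pipeline and write a report bundle
#'
#' End-to-end orchestration: obtain the population (simulate from a
#' [sim_config()], or read a CSV through a [column_mapping()]), derive the
#' schedule outcomes, rank, compute every equity metric under the requested
#' ranking kinds, decompose, and write the report tables:
#' `metrics.csv` (one row per outcome x ranking), `stratum_coverage.csv`,
#' `decomposition.csv` (long: outcome, group, share), and `run_log.txt`
#' (seed, counts, recode/missingness tallies). Deterministic given the
#' configuration and seed.
#'
#' @param config list with fields `input` (a `sim_config`, a data frame, or
#'   a CSV path), optional `mapping` ([column_mapping()] for CSV input),
#'   `schedule`, `spec`, `outcomes` (default: all doses + ZERO/FULL/
#'   COMPLETE), `ranking` (default both kinds), `seed`, `conf_mode`.
#' @param output_dir directory for the report bundle (created if needed);
#'   `NULL` to skip writing.
#' @return list with `metrics`, `stratum_coverage`, `decomposition`,
#'   `fits` and `log_lines`, invisibly when writing.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  seed <- config$seed %||% 1
  schedule <- config$schedule %||% epi_schedule()
  spec <- config$spec %||% fairness_spec()
  ranking <- config$ranking %||% c("composite", "wealth")
  conf_mode <- config$conf_mode %||% "estimator"
  log_lines <- c(sprintf("seed: %d", as.integer(seed)))

  input <- config$input
  if (inherits(input, "sim_config")) {
    pop <- simulate_population(input, seed = seed)
    log_lines <- c(log_lines,
                   sprintf("simulated population: %d children", nrow(pop)))
  } else if (is.character(input) || (is.data.frame(input) &&
                                     !is.null(config$mapping))) {
    pop <- read_population(input, config$mapping)
    rl <- attr(pop, "recode_log")
    for (f in names(rl)) {
      log_lines <- c(log_lines, sprintf("recode %s: %s", f,
        paste(sprintf("%s->%d", names(rl[[f]]), as.integer(rl[[f]])),
              collapse = " ")))
    }
    log_lines <- c(log_lines, sprintf("read population: %d children", nrow(pop)))
  } else if (is.data.frame(input)) {
    pop <- input
    log_lines <- c(log_lines, sprintf("population supplied in memory: %d children",
                                      nrow(pop)))
  } else {
    stop("pipeline stage 'input': config$input must be a sim_config, data ",
         "frame or CSV path", call. = FALSE)
  }

  derived <- withCallingHandlers(
    derive_outcomes(pop, schedule,
                    zero_dose_rule = config$zero_dose_rule %||% "any_age"),
    message = function(m) {
      log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  outcomes <- config$outcomes %||% c(schedule$dose, "ZERO", "FULL", "COMPLETE")

  suite <- compute_equity_suite(pop, outcomes = outcomes, ranking = ranking,
                                schedule = schedule, spec = spec,
                                conf_mode = conf_mode)

  strata <- stratum_coverage(pop, derived, outcomes)

  dec_rows <- list()
  for (key in names(suite$fits)) {
    f <- suite$fits[[key]]
    if (is.null(f$decomposition)) next
    g <- f$decomposition$groups
    if (nrow(g) == 0) next
    dec_rows[[key]] <- rbind(
      data.frame(outcome = f$outcome, group = g$group,
                 contribution = g$contribution,
                 share_percent = g$share_percent %||% NA_real_),
      data.frame(outcome = f$outcome, group = "residual",
                 contribution = f$decomposition$residual,
                 share_percent = f$decomposition$residual_percent))
  }
  decomposition <- if (length(dec_rows)) do.call(rbind, dec_rows)
                   else data.frame()
  rownames(decomposition) <- NULL

  res <- list(metrics = suite$metrics, stratum_coverage = strata,
              decomposition = decomposition, fits = suite$fits,
              log_lines = log_lines)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$metrics, file.path(output_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$stratum_coverage,
                     file.path(output_dir, "stratum_coverage.csv"),
                     row.names = FALSE)
    utils::write.csv(res$decomposition,
                     file.path(output_dir, "decomposition.csv"),
                     row.names = FALSE)
    writeLines(res$log_lines, file.path(output_dir, "run_log.txt"))
    return(invisible(res))
  }
  res
}
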