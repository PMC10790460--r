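# Shared fixture builders. All fixtures are generated in code; sizes are kept
# small unless a test needs Monte-Carlo resolution.

# hand-built population: covariates + explicit dose receipts, weight 1
toy_population <- function(age_months, doses_received = list(),
                           schedule = epi_schedule()) {
  n <- length(age_months)
  pop <- data.frame(
    child_id = seq_len(n),
    age_months = age_months,
    sex = rep_len(c("male", "female"), n),
    region = rep_len(c("Central", "Eastern"), n),
    residence = rep_len(c("urban", "rural"), n),
    maternal_education = rep_len(c("none", "primary"), n),
    insured = rep_len(c("no", "no"), n),
    weight = rep(1, n),
    stringsAsFactors = FALSE
  )
  for (d in schedule$dose) pop[[d]] <- 0L
  for (i in seq_along(doses_received)) {
    for (d in doses_received[[i]]) pop[i, d] <- 1L
  }
  pop
}

# equal-access config: one constant receipt probability, no planted effects
equal_access_config <- function(n = 2000, intercept = 0.5) {
  sim_config(n_children = n,
             effects = list(BCG = list(intercept = intercept)))
}

# single planted unfair factor on a birth dose (no underage variation)
planted_residence_config <- function(n, log_or = log(4)) {
  sim_config(n_children = n,
             effects = list(BCG = list(intercept = 0,
                                       residence = c(urban = log_or))))
}
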