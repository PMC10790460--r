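#' Derive analysis outcomes from dose receipts and age
#'
#' Builds the per-child outcome table from a population table holding one
#' 0/1 receipt column per schedule dose:
#' \describe{
#'   \item{per-dose columns}{receipt of that dose (missing treated as not
#'     received, with a logged count).}
#'   \item{`ZERO`}{no scheduled dose received. Under the default
#'     `zero_dose_rule = "any_age"` this holds at any age, with unvaccinated
#'     children under 12 months carrying `underage_ZERO = 1` (they are
#'     at risk of becoming zero-dose rather than confirmed); under
#'     `"strict"`, ZERO is only set for children aged 12 months or more and
#'     is `NA` below.}
#'   \item{`FULL`}{child under 24 months and every dose due at their age
#'     received (`NA` at 24 months and over). A newborn with no due doses
#'     beyond the birth doses is fully immunized for age if those are
#'     received.}
#'   \item{`COMPLETE`}{child aged 24 months or more and every schedule entry
#'     received (`NA` under 24 months). The boundary child (exactly 24
#'     months) is assessed for COMPLETE.}
#' }
#' Each dose also gets an `underage_<dose>` flag: 1 when the dose is not yet
#' due at the child's age. These flags are the fair covariates of the
#' direct-unfairness model.
#'
#' @param pop data frame with `age_months` (0-59) and one column per
#'   schedule dose label.
#' @param schedule an [epi_schedule()].
#' @param zero_dose_rule `"any_age"` (default) or `"strict"` (see above).
#' @return data frame of class `outcome_table` with the dose columns,
#'   `ZERO`, `FULL`, `COMPLETE` and the underage flags; attribute
#'   `n_missing_recoded` counts missing receipts treated as not received.
#' @export
derive_outcomes <- function(pop, schedule = epi_schedule(),
                            zero_dose_rule = c("any_age", "strict")) {
  zero_dose_rule <- match.arg(zero_dose_rule)
  stopifnot(inherits(schedule, "epi_schedule"))
  pop <- as.data.frame(pop)
  if (!"age_months" %in% names(pop)) {
    stop("population table must contain 'age_months'", call. = FALSE)
  }
  if (any(pop$age_months < 0 | pop$age_months > 59)) {
    stop("age_months outside 0-59", call. = FALSE)
  }
  doses <- schedule$dose
  missing_cols <- setdiff(doses, names(pop))
  if (length(missing_cols) > 0) {
    stop("dose column(s) absent from population table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  n <- nrow(pop)
  rec <- as.matrix(pop[, doses, drop = FALSE])
  if (!all(rec %in% c(0, 1, NA))) {
    stop("dose receipt columns must be 0/1/missing", call. = FALSE)
  }
  n_missing <- sum(is.na(rec))
  if (n_missing > 0) {
    message(n_missing, " missing dose value(s) treated as not received")
    rec[is.na(rec)] <- 0
  }

  age <- pop$age_months
  due <- outer(age, schedule$due_age_months, `>=`)  # n x doses, due at age?
  colnames(due) <- doses

  out <- as.data.frame(rec)
  any_dose <- rowSums(rec) > 0
  out$ZERO <- as.integer(!any_dose)
  if (zero_dose_rule == "strict") out$ZERO[age < 12] <- NA_integer_

  ## fully immunized for age: every due dose received (under-24-month children)
  all_due_received <- rowSums(due & rec == 0) == 0
  out$FULL <- ifelse(age < 24, as.integer(all_due_received), NA_integer_)
  out$COMPLETE <- ifelse(age >= 24, as.integer(rowSums(rec) == length(doses)),
                         NA_integer_)

  for (d in doses) out[[paste0("underage_", d)]] <- as.integer(!due[, d])
  out$underage_ZERO <- as.integer(age < 12 & !any_dose)

  attr(out, "n_missing_recoded") <- n_missing
  attr(out, "zero_dose_rule") <- zero_dose_rule
  class(out) <- c("outcome_table", "data.frame")
  out
}

## outcome -> its underage flag column (NULL when none is defined)
underage_column <- function(outcome) {
  if (outcome %in% c("FULL", "COMPLETE")) return(NULL)
  paste0("underage_", outcome)
}
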