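#' Routine immunization schedule
#'
#' Ordered antigen-dose entries with due ages in days. The default encodes
#' Uganda's routine childhood (EPI) schedule: BCG and OPV birth dose at
#' birth; DPT, OPV and PCV doses 1-3 at 6, 10 and 14 weeks; the first
#' measles-containing vaccine at 9 months. Due ages are configuration, not
#' hard-coded truth: pass a different data frame to analyse another
#' programme. Due-age comparisons downstream are made in completed months
#' via `floor(due_age_days / 30.44)`, matching how household surveys store
#' child age.
#'
#' @param entries optional data frame with columns `antigen` (label),
#'   `dose_number` (integer >= 1) and `due_age_days` (integer >= 0).
#' @return An object of class `epi_schedule`: the entries plus a derived
#'   `dose` label (`"BCG"`, `"DPT3"`, ...) and `due_age_months`.
#' @examples
#' epi_schedule()
#' @export
epi_schedule <- function(entries = NULL) {
  if (is.null(entries)) {
    entries <- data.frame(
      antigen = c("BCG", "OPV",
                  "DPT", "DPT", "DPT",
                  "OPV", "OPV", "OPV",
                  "PCV", "PCV", "PCV",
                  "MCV"),
      dose_number = c(1L, 0L, 1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L, 1L),
      due_age_days = c(0L, 0L, 42L, 70L, 98L, 42L, 70L, 98L,
                       42L, 70L, 98L, 274L),
      dose = c("BCG", "OPV0", "DPT1", "DPT2", "DPT3", "OPV1", "OPV2", "OPV3",
               "PCV1", "PCV2", "PCV3", "MCV1"),
      stringsAsFactors = FALSE
    )
  }
  entries <- as.data.frame(entries)
  req <- c("antigen", "dose_number", "due_age_days")
  if (!all(req %in% names(entries))) {
    stop("schedule entries need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(entries$due_age_days < 0) || any(entries$dose_number < 0)) {
    stop("due ages and dose numbers must be non-negative", call. = FALSE)
  }
  key <- paste(entries$antigen, entries$dose_number)
  if (anyDuplicated(key)) {
    stop("duplicate (antigen, dose_number) entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  ## due ages must not decrease along a dose series
  for (a in unique(entries$antigen)) {
    sub <- entries[entries$antigen == a, ]
    sub <- sub[order(sub$dose_number), ]
    if (is.unsorted(sub$due_age_days)) {
      stop("due ages decrease within antigen '", a, "'", call. = FALSE)
    }
  }
  ## dose labels may be supplied (the default schedule keeps BCG bare);
  ## otherwise antigen + dose_number, a dose_number of 0 marking a birth dose
  if (is.null(entries$dose)) {
    entries$dose <- paste0(entries$antigen, entries$dose_number)
  }
  if (anyDuplicated(entries$dose)) {
    stop("duplicate dose labels in schedule", call. = FALSE)
  }
  entries$due_age_months <- as.integer(floor(entries$due_age_days / 30.44))
  entries <- entries[order(entries$due_age_days, entries$antigen,
                           entries$dose_number), ]
  rownames(entries) <- NULL
  structure(entries, class = c("epi_schedule", "data.frame"))
}

#' Doses due at a given age
#'
#' Entries of the schedule whose due age has been reached. Children younger
#' than a dose's due age are not expected to have received it, so it is not
#' counted against them in the fully-immunized-for-age outcome.
#'
#' @param schedule an [epi_schedule()].
#' @param age_days age in days (>= 0). Use `age_months * 30.44` if only
#'   months are recorded; [derive_outcomes()] compares in completed months.
#' @param grace_days extra days allowed before a dose counts as due
#'   (default 0).
#' @return character vector of dose labels due at that age.
#' @export
doses_due <- function(schedule, age_days, grace_days = 0) {
  stopifnot(inherits(schedule, "epi_schedule"))
  if (length(age_days) != 1 || is.na(age_days) || age_days < 0) {
    stop("age_days must be a single non-negative number", call. = FALSE)
  }
  schedule$dose[schedule$due_age_days <= age_days + grace_days]
}
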