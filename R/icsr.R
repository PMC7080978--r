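# The ICSR collection container and its validation.
#
# A collection of individual case safety reports is held in long/relational
# form: one row per report in `$reports`, one row per drug record in `$drugs`
# and one row per reaction record in `$reactions`, keyed by `report_id`.
# This mirrors how large spontaneous-report extracts are shipped and keeps
# 2x2 counting vectorized.

.report_cols <- c("report_id", "report_date", "age_years", "sex", "country",
                  "reporter_type", "report_type", "outcome", "comment_present",
                  "dechallenge", "rechallenge")
.drug_cols <- c("report_id", "drug_name", "role", "route", "indication",
                "start_date", "dose_documented")
.reaction_cols <- c("report_id", "pt_name", "onset_date")

#' Construct an ICSR collection
#'
#' Builds the relational container used throughout the package from three
#' data frames: report-level demographics, drug records and reaction records.
#'
#' @param reports data frame with columns `report_id`, `report_date`
#'   (ISO-8601 day), `age_years`, `sex`, `country`, `reporter_type`,
#'   `report_type`, `outcome`, `comment_present` (logical), `dechallenge`,
#'   `rechallenge`. Optional fields are `NA` when absent.
#' @param drugs data frame with columns `report_id`, `drug_name`, `role`
#'   (`suspected`/`concomitant`), `route` (always present; `"unreported"`
#'   when the route was not stated), `indication`, `start_date` (ISO-8601,
#'   partial dates `"2013"`/`"2013-05"` allowed), `dose_documented` (logical).
#' @param reactions data frame with columns `report_id`, `pt_name`
#'   (preferred term), `onset_date` (ISO-8601, partial allowed).
#' @param validate run [validate_icsr_set()] (default `TRUE`).
#' @return an object of class `icsr_set`
#' @export
icsr_set <- function(reports, drugs, reactions, validate = TRUE) {
  reports <- data.table::as.data.table(reports)
  drugs <- data.table::as.data.table(drugs)
  reactions <- data.table::as.data.table(reactions)

  for (nm in setdiff(.report_cols, names(reports))) {
    reports[, (nm) := if (nm == "comment_present") NA else NA_character_]
  }
  for (nm in setdiff(.drug_cols, names(drugs))) {
    drugs[, (nm) := if (nm == "dose_documented") NA else NA_character_]
  }
  for (nm in setdiff(.reaction_cols, names(reactions))) {
    reactions[, (nm) := NA_character_]
  }

  reports <- reports[, .report_cols, with = FALSE]
  drugs <- drugs[, .drug_cols, with = FALSE]
  reactions <- reactions[, .reaction_cols, with = FALSE]

  char_cols <- function(dt, cols) {
    for (cc in cols) data.table::set(dt, j = cc, value = .blank_to_na(dt[[cc]]))
  }
  char_cols(reports, setdiff(.report_cols, c("age_years", "comment_present")))
  char_cols(drugs, setdiff(.drug_cols, "dose_documented"))
  char_cols(reactions, .reaction_cols)
  reports[, age_years := as.numeric(age_years)]
  reports[, comment_present := as.logical(comment_present)]
  drugs[, dose_documented := as.logical(dose_documented)]
  # an absent route field is normalized to the explicit "unreported" level
  drugs[is.na(route), route := "unreported"]

  x <- structure(list(reports = reports, drugs = drugs, reactions = reactions),
                 class = "icsr_set")
  if (validate) validate_icsr_set(x)
  x
}

#' An empty ICSR collection
#' @return `icsr_set` with zero reports
#' @export
empty_icsr_set <- function() {
  icsr_set(
    reports = data.table::data.table(report_id = character(),
                                     report_date = character()),
    drugs = data.table::data.table(report_id = character(),
                                   drug_name = character(),
                                   role = character()),
    reactions = data.table::data.table(report_id = character(),
                                       pt_name = character()),
    validate = FALSE
  )
}

#' Validate an ICSR collection
#'
#' Enforces the schema invariants: unique report ids, one-or-more drug and
#' reaction records per report, valid enum levels, ages in `[0, 120]`,
#' parseable dates no later than the report date. Violations raise an error
#' naming the offending report ids.
#'
#' @param x `icsr_set`
#' @return `x`, invisibly
#' @export
validate_icsr_set <- function(x) {
  stopifnot(inherits(x, "icsr_set"))
  rp <- x$reports; dr <- x$drugs; rx <- x$reactions

  fail <- function(msg, ids) {
    ids <- unique(ids)
    stop(sprintf("%s [report_id: %s]", msg,
                 paste(head(ids, 10), collapse = ", ")), call. = FALSE)
  }

  if (anyNA(rp$report_id) || any(rp$report_id == ""))
    stop("report_id must be non-empty", call. = FALSE)
  if (anyDuplicated(rp$report_id))
    fail("duplicate report_id", rp$report_id[duplicated(rp$report_id)])

  bad_date <- !.is_valid_date_str(rp$report_date) |
    .date_precision(rp$report_date) != "day"
  if (any(bad_date)) fail("report_date must be a full ISO-8601 date",
                          rp$report_id[bad_date])

  bad_age <- !is.na(rp$age_years) & (rp$age_years < 0 | rp$age_years > 120)
  if (any(bad_age)) fail("age_years outside [0, 120]", rp$report_id[bad_age])

  .assert_enum(rp$sex, .vs_sexes, "sex")
  .assert_enum(rp$reporter_type, .vs_reporter_types, "reporter_type")
  .assert_enum(rp$report_type, .vs_report_types, "report_type")
  .assert_enum(rp$outcome, .vs_outcomes, "outcome")
  .assert_enum(rp$dechallenge, .vs_challenge, "dechallenge")
  .assert_enum(rp$rechallenge, .vs_challenge, "rechallenge")

  if (nrow(rp)) {
    no_drug <- setdiff(rp$report_id, dr$report_id)
    if (length(no_drug)) fail("report without drug records", no_drug)
    no_rx <- setdiff(rp$report_id, rx$report_id)
    if (length(no_rx)) fail("report without reaction records", no_rx)
  }
  orphan <- setdiff(c(dr$report_id, rx$report_id), rp$report_id)
  if (length(orphan)) fail("drug/reaction records without a report", orphan)

  if (anyNA(dr$drug_name) || any(dr$drug_name == ""))
    fail("drug_name must be non-empty", dr$report_id[is.na(dr$drug_name) | dr$drug_name == ""])
  .assert_enum(dr$role, .vs_roles, "role", allow_na = FALSE)
  .assert_enum(dr$route, .vs_routes, "route", allow_na = FALSE)
  if (anyNA(rx$pt_name) || any(rx$pt_name == ""))
    fail("pt_name must be non-empty", rx$report_id[is.na(rx$pt_name) | rx$pt_name == ""])

  bad_start <- !is.na(dr$start_date) & !.is_valid_date_str(dr$start_date)
  if (any(bad_start)) fail("unparseable start_date", dr$report_id[bad_start])
  bad_onset <- !is.na(rx$onset_date) & !.is_valid_date_str(rx$onset_date)
  if (any(bad_onset)) fail("unparseable onset_date", rx$report_id[bad_onset])

  # every drug/reaction date precedes (or equals) the report date
  rep_date <- as.Date(rp$report_date)
  names(rep_date) <- rp$report_id
  if (nrow(dr)) {
    late <- !is.na(dr$start_date) &
      .date_floor(dr$start_date) > rep_date[dr$report_id]
    if (any(late)) fail("start_date after report_date", dr$report_id[late])
  }
  if (nrow(rx)) {
    late <- !is.na(rx$onset_date) &
      .date_floor(rx$onset_date) > rep_date[rx$report_id]
    if (any(late)) fail("onset_date after report_date", rx$report_id[late])
  }
  invisible(x)
}

#' Number of reports in a collection
#' @param x `icsr_set`
#' @return integer count
#' @export
n_reports <- function(x) nrow(x$reports)

#' Subset a collection by report id
#'
#' Keeps the given reports together with their drug and reaction records.
#' Used by all cohort filters, so filter outputs are always subsets of their
#' inputs.
#'
#' @param x `icsr_set`
#' @param ids character vector of report ids to keep
#' @return `icsr_set`
#' @export
subset_reports <- function(x, ids) {
  structure(list(
    reports = x$reports[report_id %in% ids],
    drugs = x$drugs[report_id %in% ids],
    reactions = x$reactions[report_id %in% ids]
  ), class = "icsr_set")
}

#' @export
print.icsr_set <- function(x, ...) {
  cat(sprintf("<icsr_set> %d reports, %d drug records, %d reaction records\n",
              nrow(x$reports), nrow(x$drugs), nrow(x$reactions)))
  invisible(x)
}
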