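# Cohort filters. All filters return subsets of their input (they never
# invent records) and commute with one another.

#' Select reports exposed to given drugs by a given route
#'
#' A report is exposed when at least one of its drug records has the
#' requested role (default `suspected`), a drug name in `drug_names`
#' (case-insensitive exact match on the generic name) and the requested
#' route. Reports whose only matching drug record carries route
#' `"unreported"` are excluded: a route that was not specifically reported
#' cannot establish the exposure of interest.
#'
#' @param x `icsr_set`
#' @param drug_names non-empty character vector of generic names
#' @param route required route of administration (default `"intravitreal"`)
#' @param role drug role required for exposure; the default `"suspected"`
#'   reflects the usual signal-detection convention, `"any"` relaxes it
#' @return `icsr_set` of exposed reports (possibly empty)
#' @export
select_exposed <- function(x, drug_names, route = "intravitreal",
                           role = c("suspected", "any")) {
  role <- match.arg(role)
  if (!length(drug_names)) stop("drug_names must be non-empty", call. = FALSE)
  .assert_enum(route, .vs_routes, "route", allow_na = FALSE)
  dr <- x$drugs
  hit <- tolower(dr$drug_name) %in% tolower(drug_names) & dr$route == route
  if (role == "suspected") hit <- hit & dr$role == "suspected"
  subset_reports(x, unique(dr$report_id[hit]))
}

#' Filter reports to a study period
#'
#' Retains reports whose date lies in the closed interval `[start, end]`.
#' By default the receipt (`report_date`) is used, matching extraction of a
#' spontaneous-report database by reporting period; `date_field` can be
#' switched to the earliest reaction onset for sensitivity analyses.
#'
#' @param x `icsr_set`
#' @param start,end ISO-8601 dates (or `Date`), `start <= end`
#' @param date_field `"report_date"` (default) or `"onset_date"`
#' @return `icsr_set`
#' @export
filter_period <- function(x, start, end,
                          date_field = c("report_date", "onset_date")) {
  date_field <- match.arg(date_field)
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("unparseable period bound", call. = FALSE)
  if (start > end) stop("start must be <= end", call. = FALSE)
  if (date_field == "report_date") {
    d <- as.Date(x$reports$report_date)
    ids <- x$reports$report_id[d >= start & d <= end]
  } else {
    onset <- x$reactions[!is.na(onset_date),
                         .(d = min(.date_floor(onset_date))), by = report_id]
    ids <- onset[d >= start & d <= end, report_id]
  }
  subset_reports(x, ids)
}

#' Filter reports by age
#'
#' Retains reports with a recorded age in `[min_age, max_age]` (upper bound
#' dropped when `max_age` is `NULL`). Reports with missing age are excluded
#' from any age-restricted cohort: membership of the restricted population
#' cannot be verified for them.
#'
#' @param x `icsr_set`
#' @param min_age lower bound in years, `>= 0`
#' @param max_age optional inclusive upper bound; age bands such as
#'   65-74 / >= 75 are formed with `max_age = 74` and `min_age = 75`
#' @return `icsr_set`
#' @export
filter_age <- function(x, min_age, max_age = NULL) {
  stopifnot(min_age >= 0)
  a <- x$reports$age_years
  keep <- !is.na(a) & a >= min_age
  if (!is.null(max_age)) keep <- keep & a <= max_age
  subset_reports(x, x$reports$report_id[keep])
}

#' Filter reports by sex
#'
#' Reports with missing sex are excluded from sex-restricted cohorts.
#'
#' @param x `icsr_set`
#' @param sex `"male"` or `"female"`
#' @return `icsr_set`
#' @export
filter_sex <- function(x, sex) {
  .assert_enum(sex, .vs_sexes, "sex", allow_na = FALSE)
  subset_reports(x, x$reports$report_id[!is.na(x$reports$sex) &
                                          x$reports$sex == sex])
}
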