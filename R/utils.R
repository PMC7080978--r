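# Shared helpers: enum constants, rounding, partial ISO-8601 dates.

#' @import data.table
#' @importFrom stats rexp runif sd quantile qnorm qgamma median
#' @importFrom utils head
NULL

# Enumerations of the report schema. `route` is always present on a drug
# record: "unreported" is a value, not an absent field.
.vs_routes         <- c("intravitreal", "oral", "intravenous", "other", "unreported")
.vs_roles          <- c("suspected", "concomitant")
.vs_sexes          <- c("male", "female")
.vs_reporter_types <- c("physician", "pharmacist", "consumer", "other")
.vs_report_types   <- c("spontaneous", "study", "other")
.vs_outcomes       <- c("recovered", "recovering", "not_recovered", "fatal", "unknown")
.vs_challenge      <- c("positive", "negative", "not_done", "unknown")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for all human-readable percentages in reports
#' (R's `round()` rounds half to even, which would print 0.335 as 0.34 or
#' 0.33 depending on binary representation).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with standardized rounding
#'
#' @param num numerator count
#' @param den denominator count (> 0)
#' @param digits decimal places (default 2)
#' @return `100 * num / den`, rounded half away from zero
#' @export
pct <- function(num, den, digits = 2) {
  stopifnot(all(den > 0))
  round_half_up(100 * num / den, digits)
}

# --- partial ISO-8601 dates ------------------------------------------------
# Onset and drug-start dates may be year ("2013"), month ("2013-05") or day
# ("2013-05-07") precision. Stored as character; these helpers classify and
# floor them. Precision matters for time-to-onset estimability and for the
# completeness score.

.date_precision <- function(x) {
  out <- rep(NA_character_, length(x))
  out[grepl("^\\d{4}$", x)] <- "year"
  out[grepl("^\\d{4}-\\d{2}$", x)] <- "month"
  out[grepl("^\\d{4}-\\d{2}-\\d{2}$", x)] <- "day"
  out
}

.date_is_precise <- function(x) !is.na(x) & .date_precision(x) == "day"

# Floor a (possibly partial) ISO date to a Date; NA for missing/unparseable.
.date_floor <- function(x) {
  prec <- .date_precision(x)
  full <- ifelse(is.na(prec), NA_character_,
                 ifelse(prec == "year", paste0(x, "-01-01"),
                        ifelse(prec == "month", paste0(x, "-01"), x)))
  as.Date(full)
}

.is_valid_date_str <- function(x) {
  ok <- !is.na(.date_precision(x))
  ok[ok] <- !is.na(.date_floor(x[ok]))
  ok
}

# Coerce "" to NA for optional character fields read from CSV.
.blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  x
}

.assert_enum <- function(x, allowed, field, allow_na = TRUE) {
  bad <- !is.na(x) & !(x %in% allowed)
  if (!allow_na) bad <- bad | is.na(x)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", field,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
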