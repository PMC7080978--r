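# Case-level grading: multiplicative completeness score, WHO-UMC style
# causality classification, and time-to-onset summaries.

#' Default completeness penalties
#'
#' Multiplicative penalty per missing documentation dimension. The score of
#' a report is the product of `(1 - penalty)` over the dimensions it fails:
#' time-to-onset (not computable from a precise drug start and reaction
#' onset date) weighs 0.5; indication and outcome 0.3; age, sex, dose
#' documentation, country, primary reporter, report type and free-text
#' comment 0.1 each.
#'
#' @return named numeric vector of penalties
#' @export
vigigrade_penalties <- function() {
  c(time_to_onset = 0.5, indication = 0.3, outcome = 0.3,
    sex = 0.1, age = 0.1, dose = 0.1, country = 0.1,
    reporter = 0.1, report_type = 0.1, comment = 0.1)
}

#' Completeness score per report
#'
#' Scores every report of a collection. A score of 1 means all ten
#' dimensions are documented; a report is considered well documented when
#' the score exceeds 0.8. Time-to-onset counts as documented only when the
#' report carries at least one drug record with a day-precise start date
#' *and* at least one reaction with a day-precise onset date; year- or
#' month-level dates are imprecise and penalized.
#'
#' @param x `icsr_set`
#' @param penalties named penalty vector, see [vigigrade_penalties()]
#' @return `data.table` with `report_id`, one logical `miss_*` column per
#'   dimension, `score` and `well_documented`
#' @export
vigigrade <- function(x, penalties = vigigrade_penalties()) {
  stopifnot(all(names(vigigrade_penalties()) %in% names(penalties)),
            all(penalties > 0 & penalties < 1))
  rp <- x$reports
  dr <- x$drugs
  rx <- x$reactions

  has_start <- dr[, .(ok = any(.date_is_precise(start_date))), by = report_id]
  has_onset <- rx[, .(ok = any(.date_is_precise(onset_date))), by = report_id]
  has_ind <- dr[role == "suspected",
                .(ok = any(!is.na(indication))), by = report_id]
  has_dose <- dr[, .(ok = any(dose_documented %in% TRUE)), by = report_id]
  lk <- function(tab) {
    v <- rp$report_id %in% tab$report_id[tab$ok]
    v
  }

  out <- data.table::data.table(
    report_id = rp$report_id,
    miss_time_to_onset = !(lk(has_start) & lk(has_onset)),
    miss_indication = !lk(has_ind),
    miss_outcome = is.na(rp$outcome),
    miss_sex = is.na(rp$sex),
    miss_age = is.na(rp$age_years),
    miss_dose = !lk(has_dose),
    miss_country = is.na(rp$country),
    miss_reporter = is.na(rp$reporter_type),
    miss_report_type = is.na(rp$report_type),
    miss_comment = !(rp$comment_present %in% TRUE)
  )
  dims <- names(vigigrade_penalties())
  m <- as.matrix(out[, paste0("miss_", dims), with = FALSE])
  out[, score := exp(m %*% log(1 - penalties[dims]))[, 1]]
  out[, well_documented := score > 0.8]
  out[]
}

#' WHO-UMC style causality classification
#'
#' First-match over the ordered rules:
#' \enumerate{
#'   \item insufficient or contradictory information → `unassessable`
#'   \item plausible timing, other explanations excluded, positive
#'     dechallenge *and* positive rechallenge → `certain`
#'   \item plausible timing, other explanations excluded, positive
#'     dechallenge, rechallenge not positive → `probable`
#'   \item plausible timing, other explanations possible or unknown →
#'     `possible`
#'   \item implausible timing, or another explanation likely → `unlikely`
#'   \item otherwise → `conditional`
#' }
#' All arguments are vectorized and recycled to a common length.
#'
#' @param temporal_relationship `"plausible"`, `"implausible"` or `"unknown"`
#' @param other_explanations `"excluded"`, `"possible"`, `"likely"` or
#'   `"unknown"`
#' @param dechallenge,rechallenge `"positive"`, `"negative"`, `"not_done"`
#'   or `"unknown"`
#' @param information_sufficient logical
#' @param information_contradictory logical
#' @return character vector of categories among `certain`, `probable`,
#'   `possible`, `unlikely`, `conditional`, `unassessable`
#' @export
classify_causality <- function(temporal_relationship, other_explanations,
                               dechallenge = "unknown",
                               rechallenge = "unknown",
                               information_sufficient = TRUE,
                               information_contradictory = FALSE) {
  .assert_enum(temporal_relationship, c("plausible", "implausible", "unknown"),
               "temporal_relationship", allow_na = FALSE)
  .assert_enum(other_explanations, c("excluded", "possible", "likely", "unknown"),
               "other_explanations", allow_na = FALSE)
  .assert_enum(dechallenge, .vs_challenge, "dechallenge", allow_na = FALSE)
  .assert_enum(rechallenge, .vs_challenge, "rechallenge", allow_na = FALSE)

  n <- max(lengths(list(temporal_relationship, other_explanations,
                        dechallenge, rechallenge, information_sufficient,
                        information_contradictory)))
  tr <- rep_len(temporal_relationship, n)
  oe <- rep_len(other_explanations, n)
  de <- rep_len(dechallenge, n)
  re <- rep_len(rechallenge, n)
  suff <- rep_len(information_sufficient, n)
  contra <- rep_len(information_contradictory, n)

  out <- rep("conditional", n)
  done <- rep(FALSE, n)
  rule <- function(cond, label) {
    hit <- !done & cond
    out[hit] <<- label
    done <<- done | hit
  }
  rule(!suff | contra, "unassessable")
  rule(tr == "plausible" & oe == "excluded" & de == "positive" &
         re == "positive", "certain")
  rule(tr == "plausible" & oe == "excluded" & de == "positive" &
         re != "positive", "probable")
  rule(tr == "plausible" & oe %in% c("possible", "unknown"), "possible")
  rule(tr == "implausible" | oe == "likely", "unlikely")
  out
}

#' Time-to-onset summary for a drug-event case series
#'
#' For each case the onset interval is the time from the start date of the
#' (earliest, day-precise) suspected drug record naming `drug` to the
#' (earliest, day-precise) onset date of a reaction matching `event`, in
#' years of 365.25 days. A case is estimable only when both dates are
#' present and day-precise; with `allow_report_date_fallback = TRUE` the
#' report date stands in for a missing reaction onset date.
#'
#' @param x `icsr_set` of cases (all should carry the drug and the event;
#'   non-matching reports are ignored with the estimable count unaffected
#'   only if they match)
#' @param drug generic drug name
#' @param dictionary `term_dictionary`
#' @param event `event_def`
#' @param allow_report_date_fallback see above (default `FALSE`)
#' @return list with `n_cases`, `n_estimable`, `mean_years`, `sd_years`
#'   (`NA` when not estimable; the sample SD uses the n-1 denominator and is
#'   `NA` for fewer than two estimable cases) and `onsets_years`
#' @export
time_to_onset_summary <- function(x, drug, dictionary, event,
                                  allow_report_date_fallback = FALSE) {
  members <- event_member_pts(dictionary, event)
  case_ids <- intersect(
    unique(x$drugs$report_id[tolower(x$drugs$drug_name) == tolower(drug) &
                               x$drugs$role == "suspected"]),
    unique(x$reactions$report_id[tolower(x$reactions$pt_name) %in% members]))

  onsets <- rep(NA_real_, length(case_ids))
  for (i in seq_along(case_ids)) {
    id <- case_ids[i]
    st <- x$drugs[report_id == id & tolower(drug_name) == tolower(drug) &
                    role == "suspected", start_date]
    st <- st[.date_is_precise(st)]
    on <- x$reactions[report_id == id & tolower(pt_name) %in% members,
                      onset_date]
    on <- on[.date_is_precise(on)]
    if (!length(on) && allow_report_date_fallback)
      on <- x$reports[report_id == id, report_date]
    if (length(st) && length(on)) {
      onsets[i] <- as.numeric(min(as.Date(on)) - min(as.Date(st))) / 365.25
    }
  }
  est <- onsets[!is.na(onsets)]
  list(n_cases = length(case_ids),
       n_estimable = length(est),
       mean_years = if (length(est)) mean(est) else NA_real_,
       sd_years = if (length(est) >= 2) sd(est) else NA_real_,
       onsets_years = est)
}
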