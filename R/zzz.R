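#' @importFrom stats setNames
#' @importFrom utils str capture.output packageVersion
#' @importFrom tools md5sum
NULL

# data.table NSE column names used throughout
utils::globalVariables(c(
  ".", ".N", "N", "report_id", "report_date", "age_years", "sex", "country",
  "reporter_type", "report_type", "outcome", "comment_present", "dechallenge",
  "rechallenge", "drug_name", "role", "route", "indication", "start_date",
  "dose_documented", "pt_name", "onset_date", "drug_role", "drug_route",
  "drug_indication", "drug_start_date", "smq_name", "scope", "d",
  "elderly_multiplier", "p_route_unreported", "age_mult_per_decade",
  "row_idx", "score", "well_documented", "n", "computed", "signal",
  "stratum", "event_level", "event_name", "drug"
))

.datatable.aware <- TRUE
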