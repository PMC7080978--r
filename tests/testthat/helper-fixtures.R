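# Compact builders for hand-enumerated fixtures.

# One report with a single drug and a single reaction, all arguments
# overridable; returns the three one-row frames.
mk_icsr <- function(id, date = "2013-06-15", age = 70, sex = "male",
                    country = "IT", reporter = "physician",
                    rtype = "spontaneous", outcome = "not_recovered",
                    comment = TRUE, dech = NA, rech = NA,
                    drug = "ranibizumab", role = "suspected",
                    route = "intravitreal", indication = "AMD",
                    start = "2011-02-01", dose = TRUE,
                    pt = "Parkinson's disease", onset = "2013-05-01") {
  list(
    reports = data.frame(report_id = id, report_date = date, age_years = age,
                         sex = sex, country = country, reporter_type = reporter,
                         report_type = rtype, outcome = outcome,
                         comment_present = comment, dechallenge = dech,
                         rechallenge = rech, stringsAsFactors = FALSE),
    drugs = data.frame(report_id = id, drug_name = drug, role = role,
                       route = route, indication = indication,
                       start_date = start, dose_documented = dose,
                       stringsAsFactors = FALSE),
    reactions = data.frame(report_id = id, pt_name = pt, onset_date = onset,
                           stringsAsFactors = FALSE)
  )
}

# Assemble several mk_icsr() pieces (or extra drug/reaction rows) into a set.
bind_icsrs <- function(..., validate = TRUE) {
  parts <- list(...)
  icsr_set(
    reports = data.table::rbindlist(lapply(parts, `[[`, "reports"), fill = TRUE),
    drugs = data.table::rbindlist(lapply(parts, `[[`, "drugs"), fill = TRUE),
    reactions = data.table::rbindlist(lapply(parts, `[[`, "reactions"),
                                      fill = TRUE),
    validate = validate
  )
}

tiny_dict <- function() {
  term_dictionary(data.frame(
    pt_name = c("Parkinson's disease", "Hypertonia", "Akinesia", "Tremor",
                "Dementia", "Memory impairment"),
    smq_name = c(rep("Parkinson-like events", 4), rep("Dementia", 2)),
    scope = c("narrow", "narrow", "narrow", "broad", "narrow", "broad")))
}

demo_dict <- function() {
  load_dictionary(system.file("extdata", "smq_demo.csv",
                              package = "vigisignal"))
}

# Small generator config; overridable pieces for property tests.
quick_config <- function(n = 20000, seed = 1,
                         p_drug = 0.01, elderly_mult = 1,
                         baseline = 0.02, age_mult = 1,
                         rrr = NULL, p_unrep = 0.1,
                         prop_ge65 = 0.2, miss = list(), ...) {
  generator_config(
    n_reports = n, seed = seed,
    drugs = data.frame(name = "ranibizumab", p_report = p_drug,
                       route = "intravitreal", p_route_unreported = p_unrep,
                       elderly_multiplier = elderly_mult),
    events = data.frame(pt_name = "Parkinson's disease",
                        baseline_p = baseline,
                        age_mult_per_decade = age_mult),
    planted = if (!is.null(rrr))
      data.frame(drug_name = "ranibizumab", pt_name = "Parkinson's disease",
                 rrr = rrr),
    age = list(prop_ge65 = prop_ge65, young = c(18, 64), old = c(65, 90)),
    missingness = miss, ...)
}

# PRR/cells from a generated set, via the package's analysis path.
screen_pair <- function(x, dict = tiny_dict(), drug = "ranibizumab",
                        pt = "Parkinson's disease", stratum = list()) {
  cohort <- if (length(stratum))
    filter_age(x, stratum$min_age %||% 0, stratum$max_age) else x
  tb <- build_table(cohort,
                    select_exposed(cohort, drug)$reports$report_id,
                    dict, event_def("pt", pt), drug = drug)
  screen_signals(list(tb))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent rule-table oracle for the causality classifier: the six
# category predicates evaluated over the whole grid, picked by precedence
causality_oracle <- function(g) {
  pred <- list(
    unassessable = !g$suff | g$contra,
    certain = g$tr == "plausible" & g$oe == "excluded" &
      g$de == "positive" & g$re == "positive",
    probable = g$tr == "plausible" & g$oe == "excluded" &
      g$de == "positive" & g$re != "positive",
    possible = g$tr == "plausible" & g$oe %in% c("possible", "unknown"),
    unlikely = g$tr == "implausible" | g$oe == "likely",
    conditional = rep(TRUE, nrow(g)))
  first <- apply(do.call(cbind, pred), 1, which.max)
  names(pred)[first]
}

# random non-degenerate 2x2 tables for property tests
random_tables <- function(n, seed, min_cell = 1L, max_cell = 500L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- sample(min_cell:max_cell, 4, replace = TRUE)
    structure(list(a = v[1], b = v[2], c = v[3], d = v[4],
                   n_total = sum(v), n_drug = v[1] + v[2],
                   n_event = v[1] + v[3], drug = "x",
                   event = event_def("pt", "y"), stratum = "all_ages"),
              class = "contingency_table")
  })
}
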