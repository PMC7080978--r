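# End-to-end study orchestration from a single config: cohort funnel,
# screening per stratum, case grading for flagged signals, run manifest.

#' Build and validate a study configuration
#'
#' Accepts either a named list or a path to a YAML/JSON file with the same
#' structure.
#'
#' Fields: `input` (path) and `dialect` (`jsonl`/`flat_csv`) — or the
#' collection may be passed directly to [run_screen()]; `dictionary`
#' (path to the term CSV); `drugs` (generic names); `route`; `events`
#' (list of `smqs`, `scope`, and logical `pt_level` enabling the per-PT
#' analysis over all member terms); `period` (`start`, `end`); `strata`
#' (named list of specs with optional `min_age`, `max_age`, `sex`);
#' `min_cases` (default 3); `z` (default 1.959964);
#' `exclude_class_from_comparator`; `suppress_small_cells` (mask case-level
#' tables with 10 cases or fewer; default off, meant for real data);
#' `out_dir` (optional output directory).
#'
#' @param config named list or file path
#' @return validated list of class `study_config`
#' @export
study_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(dialect = "jsonl", route = "intravitreal", role = "suspected",
                   min_cases = 3L, z = 1.959964,
                   exclude_class_from_comparator = FALSE,
                   suppress_small_cells = FALSE, small_cell_threshold = 10L,
                   ic_method = "approx",
                   strata = list(all_ages = list(), ge65 = list(min_age = 65)),
                   events = list(scope = "narrow", pt_level = TRUE))
  for (nm in names(defaults)) config[[nm]] <- config[[nm]] %||% defaults[[nm]]
  config$events$scope <- config$events$scope %||% "narrow"
  config$events$pt_level <- config$events$pt_level %||% TRUE
  if (is.null(config$drugs) || !length(config$drugs))
    stop("study_config needs at least one drug of interest", call. = FALSE)
  if (is.null(config$events$smqs) || !length(config$events$smqs))
    stop("study_config needs at least one SMQ", call. = FALSE)
  if (anyDuplicated(names(config$strata)))
    stop("stratum labels must be unique", call. = FALSE)
  structure(config, class = "study_config")
}

# event definitions implied by a config: SMQs first, then (optionally) every
# member PT of those SMQs at PT level
.config_events <- function(config, dictionary) {
  evs <- lapply(config$events$smqs, function(s)
    event_def("smq", s, config$events$scope))
  if (isTRUE(config$events$pt_level)) {
    pts <- unique(unlist(lapply(evs, function(e)
      event_member_pts(dictionary, e))))
    e <- dictionary$entries
    proper <- unique(e$pt_name[tolower(e$pt_name) %in% pts])
    evs <- c(evs, lapply(proper, function(p) event_def("pt", p)))
  }
  evs
}

#' Run the full screening study
#'
#' Executes period filter, exposure selection, event mapping, contingency
#' construction per stratum and disproportionality screening; for flagged
#' signals only, computes case-level completeness scores, causality
#' categories (derived from the structured dechallenge/rechallenge and date
#' fields) and time-to-onset summaries. When `config$out_dir` is set,
#' writes `signals.csv`, `tables.csv`, `grading.csv`, `manifest.json` and
#' `report.md` there; outputs are byte-identical across re-runs of the same
#' config and input.
#'
#' @param config `study_config` (or list/path coercible to one)
#' @param reports optional `icsr_set`; read from `config$input` when absent
#' @param dictionary optional `term_dictionary`; loaded from
#'   `config$dictionary` when absent
#' @return list of class `study_results` with `signals`, `tables`, `funnel`,
#'   `grading`, `tto`, `manifest` (zero exposed reports yields an empty but
#'   well-formed result, not an error)
#' @export
run_screen <- function(config, reports = NULL, dictionary = NULL) {
  if (!inherits(config, "study_config")) config <- study_config(config)
  if (is.null(reports)) reports <- read_reports(config$input, config$dialect)
  if (is.null(dictionary)) dictionary <- load_dictionary(config$dictionary)

  funnel <- list(total = n_reports(reports))
  if (!is.null(config$period)) {
    reports <- filter_period(reports, config$period$start, config$period$end)
  }
  funnel$in_period <- n_reports(reports)
  exposed_all <- select_exposed(reports, config$drugs, route = config$route,
                                role = config$role)
  funnel$exposed <- n_reports(exposed_all)

  evs <- .config_events(config, dictionary)
  for (e in evs) {
    if (e$level == "smq") {
      funnel[[paste0("exposed_smq_", gsub("\\W+", "_", tolower(e$name)))]] <-
        sum(event_matches(exposed_all, dictionary, e))
    }
  }

  if (funnel$exposed == 0L) {
    message("no exposed reports after filtering; returning empty result")
    res <- structure(list(signals = screen_signals(list()),
                          tables = list(), funnel = funnel,
                          grading = data.table::data.table(), tto = list(),
                          manifest = .manifest(config, funnel)),
                     class = "study_results")
    if (!is.null(config$out_dir)) .write_outputs(res, config)
    return(res)
  }

  tables <- enumerate_tables(
    reports, dictionary, config$drugs, evs, strata = config$strata,
    route = config$route, role = config$role,
    exclude_class_from_comparator = config$exclude_class_from_comparator)
  signals <- screen_signals(tables, min_cases = config$min_cases,
                            z = config$z, ic_method = config$ic_method)

  # case grading and time-to-onset only where a signal was flagged
  grading_rows <- list(); tto <- list()
  sig <- signals[signal == TRUE]
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      ev <- event_def(sig$event_level[i], sig$event_name[i],
                      config$events$scope)
      cohort <- .apply_stratum(reports, config$strata[[sig$stratum[i]]])
      cases <- subset_reports(
        select_exposed(cohort, sig$drug[i], route = config$route,
                       role = config$role),
        matching_ids(cohort, dictionary, ev))
      vg <- vigigrade(cases)
      ca <- .derive_causality(cases)
      key <- sprintf("%s|%s:%s|%s", sig$drug[i], sig$event_level[i],
                     sig$event_name[i], sig$stratum[i])
      tto[[key]] <- time_to_onset_summary(cases, sig$drug[i], dictionary, ev)
      grading_rows[[key]] <- data.table::data.table(
        drug = sig$drug[i], event_level = sig$event_level[i],
        event_name = sig$event_name[i], stratum = sig$stratum[i],
        report_id = vg$report_id, completeness_score = vg$score,
        well_documented = vg$well_documented, causality_category = ca)
    }
  }
  grading <- data.table::rbindlist(grading_rows)
  if (isTRUE(config$suppress_small_cells) && nrow(grading)) {
    small <- grading[, .N, by = .(drug, event_level, event_name, stratum)][
      N <= config$small_cell_threshold]
    if (nrow(small)) {
      grading <- grading[!small, on = c("drug", "event_level", "event_name",
                                        "stratum")]
    }
  }

  res <- structure(list(signals = signals, tables = tables, funnel = funnel,
                        grading = grading, tto = tto,
                        manifest = .manifest(config, funnel)),
                   class = "study_results")
  if (!is.null(config$out_dir)) .write_outputs(res, config)
  res
}

# Causality inputs derived from the structured fields of synthetic/real
# reports: timing is plausible when a day-precise onset does not precede a
# day-precise drug start, implausible when it does, otherwise unknown;
# alternative explanations are unknown (no narrative mining); information is
# sufficient when timing could be assessed or a dechallenge is recorded.
.derive_causality <- function(cases) {
  vapply(cases$reports$report_id, function(id) {
    st <- cases$drugs[report_id == id & role == "suspected", start_date]
    st <- st[.date_is_precise(st)]
    on <- cases$reactions[report_id == id, onset_date]
    on <- on[.date_is_precise(on)]
    temporal <- if (length(st) && length(on)) {
      if (min(as.Date(on)) >= min(as.Date(st))) "plausible" else "implausible"
    } else "unknown"
    rp <- cases$reports[report_id == id]
    de <- if (is.na(rp$dechallenge)) "unknown" else rp$dechallenge
    re <- if (is.na(rp$rechallenge)) "unknown" else rp$rechallenge
    suff <- temporal != "unknown" || de != "unknown"
    classify_causality(temporal, "unknown", de, re,
                       information_sufficient = suff)
  }, character(1))
}

.manifest <- function(config, funnel) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  list(config_hash = .hash_obj(cfg), funnel = funnel,
       package_version = as.character(utils::packageVersion("vigisignal")))
}

# Deterministic content hash of the effective config (md5 of its printed
# structure); avoids a digest dependency.
.hash_obj <- function(x) {
  txt <- utils::capture.output(str(x, vec.len = 1e6, digits.d = 15))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

.write_outputs <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_signals(res$signals, p("signals.csv"))
  if (length(res$tables)) write_tables(res$tables, p("tables.csv"))
  if (nrow(res$grading)) data.table::fwrite(res$grading, p("grading.csv"),
                                            na = "NA")
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(run_report(res), p("report.md"))
  invisible(config$out_dir)
}
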