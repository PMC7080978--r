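# 2x2 contingency construction: exposed/unexposed by event/no-event within a
# stratum cohort, the comparator being all other reports of the same cohort.

#' Build one 2x2 contingency table
#'
#' Partitions the stratum cohort into the four cells of the drug-event table:
#' `a` exposed with the event, `b` exposed without, `c` unexposed with the
#' event, `d` the remainder. Every report falls in exactly one cell, so
#' `a + b + c + d` equals the cohort size and the margins are the exposure
#' and event counts.
#'
#' @param cohort `icsr_set`: the full stratum cohort (exposed and comparator)
#' @param exposed_ids report ids of the exposed set; must be a subset of the
#'   cohort's ids (typically from [select_exposed()])
#' @param dictionary `term_dictionary`
#' @param event `event_def`
#' @param drug label for the exposure (used in outputs)
#' @param stratum stratum label (e.g. `"all_ages"`, `"ge65"`)
#' @return object of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `n_total`, `n_drug`, `n_event`, `drug`, `event`, `stratum`
#' @export
build_table <- function(cohort, exposed_ids, dictionary, event,
                        drug = NA_character_, stratum = "all_ages") {
  n <- n_reports(cohort)
  if (n == 0L) stop("empty cohort", call. = FALSE)
  ids <- cohort$reports$report_id
  if (!all(exposed_ids %in% ids))
    stop("exposed_ids not a subset of the cohort", call. = FALSE)
  exposed <- ids %in% exposed_ids
  has_event <- event_matches(cohort, dictionary, event)
  a <- sum(exposed & has_event)
  b <- sum(exposed & !has_event)
  c_ <- sum(!exposed & has_event)
  d <- sum(!exposed & !has_event)
  structure(list(a = a, b = b, c = c_, d = d,
                 n_total = n, n_drug = a + b, n_event = a + c_,
                 drug = drug, event = event, stratum = stratum),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s vs %s [%s]\n  a=%d b=%d c=%d d=%d (N=%d)\n",
              x$drug, format(x$event), x$stratum, x$a, x$b, x$c, x$d,
              x$n_total))
  invisible(x)
}

# Apply one stratum spec (list with optional min_age/max_age/sex) to a
# collection. An empty spec is the all-ages cohort.
.apply_stratum <- function(x, spec) {
  if (!is.null(spec$min_age) || !is.null(spec$max_age))
    x <- filter_age(x, spec$min_age %||% 0, spec$max_age)
  if (!is.null(spec$sex)) x <- filter_sex(x, spec$sex)
  x
}

#' Enumerate contingency tables over drugs, events and strata
#'
#' Builds one table per (drug, event, stratum) triple. Within each stratum
#' the cohort is recomputed (comparator-within-stratum: an age-restricted
#' analysis compares against the background reporting of the restricted
#' population) and exposure is determined by [select_exposed()]. The
#' comparator for one study drug includes reports of the other study drugs
#' unless `exclude_class_from_comparator` is set, in which case reports
#' exposed to any *other* listed drug are dropped from that drug's cohort.
#' A report suspected for two study drugs contributes to the exposed cell of
#' each drug's table.
#'
#' Ordering is deterministic: drugs in the given order, then events with
#' SMQ-level before PT-level (stable within level), then strata in the given
#' order.
#'
#' @param x `icsr_set`: the full (period-filtered) database
#' @param dictionary `term_dictionary`
#' @param drugs character vector of generic names of interest
#' @param events list of [event_def()] objects
#' @param strata named list of stratum specs, each a list with optional
#'   `min_age`, `max_age`, `sex`; e.g.
#'   `list(all_ages = list(), ge65 = list(min_age = 65))`
#' @param route exposure route passed to [select_exposed()]
#' @param role exposure role passed to [select_exposed()]
#' @param exclude_class_from_comparator drop other study drugs' exposed
#'   reports from the comparator (default `FALSE`)
#' @return list of `contingency_table` (class `contingency_list`)
#' @export
enumerate_tables <- function(x, dictionary, drugs, events,
                             strata = list(all_ages = list()),
                             route = "intravitreal",
                             role = "suspected",
                             exclude_class_from_comparator = FALSE) {
  stopifnot(length(drugs) >= 1L, length(events) >= 1L)
  if (is.null(names(strata)) || any(!nzchar(names(strata))))
    stop("strata must be a named list", call. = FALSE)
  lv <- vapply(events, function(e) e$level, character(1))
  events <- c(events[lv == "smq"], events[lv == "pt"])

  out <- list()
  for (drug in drugs) {
    for (event in events) {
      for (sname in names(strata)) {
        cohort <- .apply_stratum(x, strata[[sname]])
        if (exclude_class_from_comparator && length(drugs) > 1L) {
          others <- setdiff(drugs, drug)
          other_ids <- select_exposed(cohort, others, route = route,
                                      role = role)$reports$report_id
          own_ids <- select_exposed(cohort, drug, route = route,
                                    role = role)$reports$report_id
          cohort <- subset_reports(
            cohort, setdiff(cohort$reports$report_id,
                            setdiff(other_ids, own_ids)))
        }
        if (n_reports(cohort) == 0L) next
        exposed <- select_exposed(cohort, drug, route = route, role = role)
        out[[length(out) + 1L]] <-
          build_table(cohort, exposed$reports$report_id, dictionary, event,
                      drug = drug, stratum = sname)
      }
    }
  }
  structure(out, class = "contingency_list")
}

#' Contingency tables as a data table
#'
#' @param x `contingency_list` (or a plain list of `contingency_table`)
#' @param keep.rownames ignored
#' @param ... ignored
#' @return `data.table` with columns `drug`, `event_level`, `event_name`,
#'   `stratum`, `a`, `b`, `c`, `d`
#' @export
as.data.table.contingency_list <- function(x, keep.rownames = FALSE, ...) {
  data.table::rbindlist(lapply(x, function(tb) list(
    drug = tb$drug, event_level = tb$event$level, event_name = tb$event$name,
    stratum = tb$stratum, a = tb$a, b = tb$b, c = tb$c, d = tb$d)))
}

#' Export contingency tables to CSV
#'
#' @param tables `contingency_list`
#' @param path destination CSV
#' @return `path`, invisibly
#' @export
write_tables <- function(tables, path) {
  data.table::fwrite(as.data.table.contingency_list(tables), path)
  invisible(path)
}
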