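# Preferred-term dictionary: PT membership of standardized query groupings
# (SMQ-style), with narrow/broad scope, and event matching of reports.
#
# The dictionary is assumed pre-rolled to PT level (no lower-level-term
# rollup). A PT may belong to several queries; (pt, smq) pairs are unique.

#' Construct a term dictionary
#'
#' @param entries data frame with columns `pt_name`, `smq_name`, `scope`
#'   (`"narrow"` or `"broad"`). Duplicate (pt, smq) pairs collapse with a
#'   warning.
#' @return object of class `term_dictionary`
#' @export
term_dictionary <- function(entries) {
  entries <- data.table::as.data.table(entries)
  need <- c("pt_name", "smq_name", "scope")
  if (!all(need %in% names(entries)))
    stop("dictionary needs columns pt_name, smq_name, scope", call. = FALSE)
  entries <- entries[, need, with = FALSE]
  for (cc in need) data.table::set(entries, j = cc,
                                   value = as.character(entries[[cc]]))
  bad <- !entries$scope %in% c("narrow", "broad")
  if (any(bad))
    stop("unknown scope value(s): ", paste(unique(entries$scope[bad]),
                                           collapse = ", "), call. = FALSE)
  dup <- duplicated(entries[, .(tolower(pt_name), tolower(smq_name))])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate dictionary entr%s", sum(dup),
                    if (sum(dup) == 1) "y" else "ies"), call. = FALSE)
    entries <- entries[!dup]
  }
  structure(list(entries = entries), class = "term_dictionary")
}

#' Load a term dictionary from CSV
#'
#' @param path CSV with columns `pt_name`, `smq_name`, `scope`
#' @return `term_dictionary`
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  term_dictionary(data.table::fread(path, colClasses = "character"))
}

#' Define an event of interest
#'
#' An event is either a single preferred term (`level = "pt"`) or a
#' standardized query (`level = "smq"`). For queries, the default scope is
#' `"narrow"` (high specificity); `"broad"` additionally includes the
#' broad-scope member terms, so broad matches are a superset of narrow ones.
#'
#' @param level `"smq"` or `"pt"`
#' @param name event name (query name or preferred term)
#' @param scope `"narrow"` (default) or `"broad"`; ignored for `level = "pt"`
#' @return object of class `event_def`
#' @export
event_def <- function(level = c("smq", "pt"), name, scope = c("narrow", "broad")) {
  level <- match.arg(level)
  scope <- match.arg(scope)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(level = level, name = name, scope = scope),
            class = "event_def")
}

#' @export
format.event_def <- function(x, ...) {
  if (x$level == "smq") sprintf("SMQ '%s' (%s)", x$name, x$scope)
  else sprintf("PT '%s'", x$name)
}

#' @export
print.event_def <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Member preferred terms of an event definition
#'
#' @param dictionary `term_dictionary`
#' @param event `event_def`
#' @return character vector of PT names (lower-cased)
#' @export
event_member_pts <- function(dictionary, event) {
  stopifnot(inherits(event, "event_def"))
  if (event$level == "pt") return(tolower(event$name))
  e <- dictionary$entries
  known <- tolower(e$smq_name)
  if (!tolower(event$name) %in% known)
    stop("SMQ not in dictionary: ", event$name, call. = FALSE)
  scopes <- if (event$scope == "broad") c("narrow", "broad") else "narrow"
  tolower(e$pt_name[known == tolower(event$name) & e$scope %in% scopes])
}

#' Which reports match an event definition
#'
#' A report matches a PT-level event when any of its reactions carries that
#' preferred term (case-insensitive), and an SMQ-level event when any
#' reaction PT is a member of the query at the requested scope. A report
#' counts at most once per event definition no matter how many matching PTs
#' it carries.
#'
#' @param x `icsr_set`
#' @param dictionary `term_dictionary`
#' @param event `event_def`
#' @return logical vector aligned with `x$reports`
#' @export
event_matches <- function(x, dictionary, event) {
  members <- event_member_pts(dictionary, event)
  hit_ids <- unique(x$reactions$report_id[tolower(x$reactions$pt_name) %in% members])
  x$reports$report_id %in% hit_ids
}

#' Report ids matching an event definition
#' @inheritParams event_matches
#' @return character vector of report ids
#' @export
matching_ids <- function(x, dictionary, event) {
  x$reports$report_id[event_matches(x, dictionary, event)]
}
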