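# Readers/writers for ICSR collections: JSON-lines (nested, one report per
# line) and a flat CSV dialect (one row per drug x reaction combination,
# re-nested on read).

.flat_csv_cols <- c("report_id", "report_date", "age_years", "sex", "country",
                    "reporter_type", "report_type", "outcome",
                    "comment_present", "dechallenge", "rechallenge",
                    "drug_name", "drug_role", "drug_route", "drug_indication",
                    "drug_start_date", "dose_documented", "pt_name",
                    "onset_date")

#' Read an ICSR collection from disk
#'
#' @param path file path
#' @param dialect `"jsonl"` (one nested report object per line) or
#'   `"flat_csv"` (one row per drug-reaction combination; rows sharing a
#'   `report_id` are re-nested into one report).
#' @return validated `icsr_set`. For `jsonl`, lines that are not valid JSON
#'   objects are rejected with a warning listing their line numbers
#'   (also available as `attr(x, "rejected_lines")`); schema violations in
#'   parsed records are errors naming the report id.
#' @export
read_reports <- function(path, dialect = c("jsonl", "flat_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "jsonl") .read_jsonl(path) else .read_flat_csv(path)
}

.scalar_or_na <- function(rec, field) {
  v <- rec[[field]]
  if (is.null(v) || length(v) == 0 || is.na(v[1])) NA else v[1]
}

.read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_icsr_set())

  recs <- vector("list", length(lines))
  bad <- logical(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec) || !is.list(rec) || is.null(rec$report_id)) {
      bad[i] <- TRUE
    } else {
      recs[[i]] <- rec
    }
  }
  if (all(bad)) stop("no parseable JSON records in ", path, call. = FALSE)
  if (any(bad)) {
    warning(sprintf("rejected %d malformed record(s) at line(s): %s",
                    sum(bad), paste(line_no[bad], collapse = ", ")),
            call. = FALSE)
  }
  recs <- recs[!bad]

  rep_rows <- data.table::rbindlist(lapply(recs, function(r) {
    as.list(sapply(setdiff(.report_cols, c("comment_present")), function(f)
      as.character(.scalar_or_na(r, f)), simplify = FALSE)) |>
      c(list(comment_present = as.logical(.scalar_or_na(r, "comment_present"))))
  }), fill = TRUE)

  dr_rows <- data.table::rbindlist(lapply(recs, function(r) {
    data.table::rbindlist(lapply(r$drugs, function(d) list(
      report_id = as.character(r$report_id),
      drug_name = as.character(.scalar_or_na(d, "drug_name")),
      role = as.character(.scalar_or_na(d, "role")),
      route = as.character(.scalar_or_na(d, "route")),
      indication = as.character(.scalar_or_na(d, "indication")),
      start_date = as.character(.scalar_or_na(d, "start_date")),
      dose_documented = as.logical(.scalar_or_na(d, "dose_documented"))
    )))
  }))
  rx_rows <- data.table::rbindlist(lapply(recs, function(r) {
    data.table::rbindlist(lapply(r$reactions, function(q) list(
      report_id = as.character(r$report_id),
      pt_name = as.character(.scalar_or_na(q, "pt_name")),
      onset_date = as.character(.scalar_or_na(q, "onset_date"))
    )))
  }))

  x <- icsr_set(rep_rows, dr_rows, rx_rows)
  attr(x, "rejected_lines") <- line_no[bad]
  x
}

.read_flat_csv <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, colClasses = "character", na.strings = c("", "NA")),
    error = function(e) stop("unparseable CSV: ", conditionMessage(e),
                             call. = FALSE))
  missing_cols <- setdiff(.flat_csv_cols, names(dt))
  if (length(missing_cols))
    stop("flat_csv missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!nrow(dt)) return(empty_icsr_set())

  demo_cols <- .report_cols
  demo <- unique(dt[, demo_cols, with = FALSE])
  conflicting <- demo[, .N, by = report_id][N > 1L, report_id]
  if (length(conflicting))
    stop("conflicting demographics for duplicated report_id: ",
         paste(head(conflicting, 10), collapse = ", "), call. = FALSE)

  drugs <- unique(dt[, .(report_id, drug_name, role = drug_role,
                         route = drug_route, indication = drug_indication,
                         start_date = drug_start_date, dose_documented)])
  reactions <- unique(dt[, .(report_id, pt_name, onset_date)])
  icsr_set(demo, drugs, reactions)
}

#' Write an ICSR collection to disk
#'
#' `read_reports(write_reports(x, ...))` is the identity on validated
#' collections, for both dialects (flat CSV round-trips through the
#' drug-by-reaction cross join and re-nesting).
#'
#' @param x validated `icsr_set`
#' @param path destination file path
#' @param dialect `"jsonl"` or `"flat_csv"`
#' @return `path`, invisibly
#' @export
write_reports <- function(x, path, dialect = c("jsonl", "flat_csv")) {
  dialect <- match.arg(dialect)
  validate_icsr_set(x)
  if (dialect == "jsonl") .write_jsonl(x, path) else .write_flat_csv(x, path)
  invisible(path)
}

.strip_na <- function(lst) lst[!vapply(lst, function(v) is.na(v), logical(1))]

.write_jsonl <- function(x, path) {
  dr_split <- split(x$drugs, by = "report_id")
  rx_split <- split(x$reactions, by = "report_id")
  con <- file(path, open = "wt")
  on.exit(close(con))
  rp <- x$reports
  for (i in seq_len(nrow(rp))) {
    id <- rp$report_id[i]
    rec <- .strip_na(as.list(rp[i]))
    rec$drugs <- lapply(seq_len(nrow(dr_split[[id]])), function(j)
      .strip_na(as.list(dr_split[[id]][j, -"report_id"])))
    rec$reactions <- lapply(seq_len(nrow(rx_split[[id]])), function(j)
      .strip_na(as.list(rx_split[[id]][j, -"report_id"])))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
}

.write_flat_csv <- function(x, path) {
  if (!nrow(x$reports)) {
    empty <- data.table::setnames(
      data.table::as.data.table(matrix(character(), ncol = length(.flat_csv_cols))),
      .flat_csv_cols)
    data.table::fwrite(empty[0], path)
    return(invisible(path))
  }
  dr <- data.table::copy(x$drugs)
  data.table::setnames(dr, c("role", "route", "indication", "start_date"),
                       c("drug_role", "drug_route", "drug_indication",
                         "drug_start_date"))
  flat <- merge(merge(x$reports, dr, by = "report_id", allow.cartesian = TRUE),
                x$reactions, by = "report_id", allow.cartesian = TRUE)
  data.table::setcolorder(flat, .flat_csv_cols)
  data.table::setkey(flat, NULL)
  data.table::fwrite(flat[order(report_id)], path)
}
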