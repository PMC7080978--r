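# Seeded generator for synthetic spontaneous-report databases.
#
# The generator emulates the structure a disproportionality screen assumes:
# a large background of unrelated reports, a rare exposure of interest with
# a declared route (sometimes unreported), preferred-term coded reactions
# whose rates may rise with age, planted drug-event reporting-rate ratios
# (RRR), realistic field missingness, and drug-start/onset dates with an
# exponential lag. `expected_cells()` gives the closed-form expected 2x2
# cells implied by a config, used as the oracle in recovery tests.

.default_missingness <- function() {
  list(age = 0.15, sex = 0.10, country = 0.05, reporter_type = 0.10,
       report_type = 0.05, outcome = 0.30, indication = 0.40,
       start_date = 0.35, start_date_imprecise = 0.15,
       onset_date = 0.20, dechallenge = 0.60, rechallenge = 0.85)
}

#' Build and validate a generator configuration
#'
#' @param n_reports number of reports to generate (>= 1)
#' @param seed integer RNG seed; identical seed and config give identical
#'   collections
#' @param drugs data frame with columns `name`, `p_report` (marginal
#'   probability that a report carries the drug as suspected), and optional
#'   `route` (default `"intravitreal"`), `p_route_unreported` (default 0.1),
#'   `elderly_multiplier` (multiplies `p_report` for ages >= 65, default 1;
#'   the lever for age-confounded exposure), `indication`
#' @param events data frame with columns `pt_name`, `baseline_p` and
#'   optional `age_mult_per_decade` (multiplier on the reporting probability
#'   per decade of age above 60, default 1)
#' @param planted optional data frame `drug_name`, `pt_name`, `rrr`:
#'   reporting-rate ratios applied multiplicatively when the drug is on the
#'   report (RRR = 1 plants nothing)
#' @param age list: `prop_ge65`, and inclusive integer bands `young`,
#'   `old` (defaults 0.20, 18-64, 65-90)
#' @param sex_ratio proportion male (default 0.45)
#' @param missingness named list of per-field absence probabilities
#'   (defaults via the package; partial overrides allowed).
#'   `start_date_imprecise` is the probability that a present start date is
#'   degraded to year precision.
#' @param period character vector `c(start, end)` of ISO dates
#' @param p_comment probability a free-text comment is present (default 0.4)
#' @param p_dose probability dose is documented (default 0.3)
#' @param onset_lag_mean_years mean of the exponential drug-start to onset
#'   lag (default 1.5)
#' @param background list with `drugs` and `pts` filler pools guaranteeing
#'   every report at least one drug and one reaction; must be disjoint from
#'   the configured event PTs
#' @param co_occur optional list(`groups` = list of PT vectors, `p`):
#'   within a group, once one member PT fires the others co-occur with
#'   probability `p` — used to make SMQ counts diverge from PT counts
#' @return validated list of class `generator_config`
#' @export
generator_config <- function(n_reports, seed, drugs, events, planted = NULL,
                             age = list(prop_ge65 = 0.20, young = c(18, 64),
                                        old = c(65, 90)),
                             sex_ratio = 0.45,
                             missingness = list(),
                             period = c("2010-01-01", "2016-12-31"),
                             p_comment = 0.4, p_dose = 0.3,
                             onset_lag_mean_years = 1.5,
                             background = list(
                               drugs = c("paracetamol", "amoxicillin",
                                         "metformin", "atorvastatin"),
                               pts = c("Nausea", "Headache", "Rash",
                                       "Dizziness", "Fatigue")),
                             co_occur = NULL) {
  drugs <- data.table::as.data.table(drugs)
  events <- data.table::as.data.table(events)
  stopifnot(n_reports >= 1, all(c("name", "p_report") %in% names(drugs)),
            all(c("pt_name", "baseline_p") %in% names(events)))
  if (!"route" %in% names(drugs)) drugs[, route := "intravitreal"]
  if (!"p_route_unreported" %in% names(drugs)) drugs[, p_route_unreported := 0.1]
  if (!"elderly_multiplier" %in% names(drugs)) drugs[, elderly_multiplier := 1]
  if (!"indication" %in% names(drugs))
    drugs[, indication := "age-related macular degeneration"]
  if (!"age_mult_per_decade" %in% names(events))
    events[, age_mult_per_decade := 1]

  m <- .default_missingness()
  unknown <- setdiff(names(missingness), names(m))
  if (length(unknown)) stop("unknown missingness field(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  m[names(missingness)] <- missingness

  probs <- c(drugs$p_report, drugs$p_route_unreported, events$baseline_p,
             unlist(m), sex_ratio, age$prop_ge65, p_comment, p_dose)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]",
                                       call. = FALSE)
  if (!is.null(planted)) {
    planted <- data.table::as.data.table(planted)
    stopifnot(all(c("drug_name", "pt_name", "rrr") %in% names(planted)),
              all(planted$rrr > 0),
              all(planted$drug_name %in% drugs$name),
              all(planted$pt_name %in% events$pt_name))
  }
  if (any(tolower(background$pts) %in% tolower(events$pt_name)))
    stop("background PTs must be disjoint from event PTs", call. = FALSE)
  if (!is.null(co_occur)) {
    stopifnot(is.list(co_occur$groups), co_occur$p >= 0, co_occur$p <= 1,
              all(unlist(co_occur$groups) %in% events$pt_name))
  }
  structure(list(n_reports = as.integer(n_reports), seed = as.integer(seed),
                 drugs = drugs, events = events, planted = planted,
                 age = age, sex_ratio = sex_ratio, missingness = m,
                 period = period, p_comment = p_comment, p_dose = p_dose,
                 onset_lag_mean_years = onset_lag_mean_years,
                 background = background, co_occur = co_occur),
            class = "generator_config")
}

# per-age event probability before planting, possibly capped later
.event_base_p <- function(baseline, mult, age) {
  baseline * mult^pmax(0, (age - 60) / 10)
}

#' Generate a synthetic report collection
#'
#' Sampling is fully vectorized under a single seeded stream, so a given
#' (config, seed) always yields the identical collection. Event
#' probabilities that exceed 1 after age and RRR multipliers are capped
#' with one warning. Generation uses the *true* sampled age; field
#' missingness only hides values afterwards, which is what makes
#' age-restricted re-analysis meaningful.
#'
#' @param config `generator_config`
#' @return validated `icsr_set`
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_reports
  m <- config$missingness
  drugs <- config$drugs
  events <- config$events

  elderly <- runif(n) < config$age$prop_ge65
  age <- integer(n)
  yb <- config$age$young; ob <- config$age$old
  age[!elderly] <- sample(yb[1]:yb[2], sum(!elderly), replace = TRUE)
  age[elderly] <- sample(ob[1]:ob[2], sum(elderly), replace = TRUE)

  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  days <- seq(as.Date(config$period[1]), as.Date(config$period[2]), by = "day")
  report_date <- sample(days, n, replace = TRUE)

  # suspected-drug incidence matrix (n x n_drugs)
  nd <- nrow(drugs)
  take <- matrix(FALSE, n, nd)
  for (j in seq_len(nd)) {
    p <- drugs$p_report[j] * ifelse(age >= 65, drugs$elderly_multiplier[j], 1)
    p <- pmin(p, 1)
    take[, j] <- runif(n) < p
  }

  # event incidence matrix (n x n_events), with planted RRRs
  ne <- nrow(events)
  pmat <- matrix(0, n, ne)
  for (k in seq_len(ne)) {
    pmat[, k] <- .event_base_p(events$baseline_p[k],
                               events$age_mult_per_decade[k], age)
  }
  if (!is.null(config$planted)) {
    for (i in seq_len(nrow(config$planted))) {
      j <- match(config$planted$drug_name[i], drugs$name)
      k <- match(config$planted$pt_name[i], events$pt_name)
      pmat[take[, j], k] <- pmat[take[, j], k] * config$planted$rrr[i]
    }
  }
  n_capped <- sum(pmat > 1)
  if (n_capped > 0)
    warning(sprintf("capped %d event probabilit%s at 1", n_capped,
                    if (n_capped == 1) "y" else "ies"), call. = FALSE)
  pmat <- pmin(pmat, 1)
  fire <- matrix(runif(n * ne), n, ne) < pmat

  if (!is.null(config$co_occur)) {
    for (grp in config$co_occur$groups) {
      ks <- match(grp, events$pt_name)
      any_fired <- rowSums(fire[, ks, drop = FALSE]) > 0
      add <- matrix(runif(n * length(ks)), n, length(ks)) < config$co_occur$p
      fire[, ks] <- fire[, ks, drop = FALSE] | (add & any_fired)
    }
  }

  report_id <- sprintf("R%07d", seq_len(n))

  # --- drug records -------------------------------------------------------
  drug_rows <- list()
  for (j in seq_len(nd)) {
    idx <- which(take[, j])
    if (!length(idx)) next
    unrep <- runif(length(idx)) < drugs$p_route_unreported[j]
    drug_rows[[length(drug_rows) + 1L]] <- data.table::data.table(
      report_id = report_id[idx],
      drug_name = drugs$name[j],
      role = "suspected",
      route = ifelse(unrep, "unreported", drugs$route[j]),
      indication = ifelse(runif(length(idx)) < m$indication, NA_character_,
                          drugs$indication[j]),
      row_idx = idx)
  }
  no_drug <- which(rowSums(take) == 0)
  if (length(no_drug)) {
    drug_rows[[length(drug_rows) + 1L]] <- data.table::data.table(
      report_id = report_id[no_drug],
      drug_name = sample(config$background$drugs, length(no_drug),
                         replace = TRUE),
      role = "suspected",
      route = sample(c("oral", "intravenous", "other"), length(no_drug),
                     replace = TRUE, prob = c(0.7, 0.2, 0.1)),
      indication = ifelse(runif(length(no_drug)) < m$indication,
                          NA_character_, "chronic condition"),
      row_idx = no_drug)
  }
  dr <- data.table::rbindlist(drug_rows)

  # drug start date: exponential lag before (report_date - 30 d), so starts
  # never postdate onsets; some missing, some degraded to year precision
  lag_days <- rexp(nrow(dr), rate = 1 / (config$onset_lag_mean_years * 365.25))
  start <- report_date[dr$row_idx] - 30L - as.integer(round(lag_days))
  start_str <- format(start, "%Y-%m-%d")
  imprec <- runif(nrow(dr)) < m$start_date_imprecise
  start_str[imprec] <- substr(start_str[imprec], 1, 4)
  start_str[runif(nrow(dr)) < m$start_date] <- NA_character_
  dr[, start_date := start_str]
  dr[, dose_documented := runif(.N) < config$p_dose]

  # --- reaction records ---------------------------------------------------
  rx_rows <- list()
  for (k in seq_len(ne)) {
    idx <- which(fire[, k])
    if (!length(idx)) next
    rx_rows[[length(rx_rows) + 1L]] <- data.table::data.table(
      report_id = report_id[idx], pt_name = events$pt_name[k], row_idx = idx)
  }
  no_event <- which(rowSums(fire) == 0)
  if (length(no_event)) {
    rx_rows[[length(rx_rows) + 1L]] <- data.table::data.table(
      report_id = report_id[no_event],
      pt_name = sample(config$background$pts, length(no_event), replace = TRUE),
      row_idx = no_event)
  }
  rx <- data.table::rbindlist(rx_rows)
  onset <- report_date[rx$row_idx] - sample(0:30, nrow(rx), replace = TRUE)
  onset_str <- format(onset, "%Y-%m-%d")
  onset_str[runif(nrow(rx)) < m$onset_date] <- NA_character_
  rx[, onset_date := onset_str]

  # --- report-level fields with missingness -------------------------------
  mask <- function(v, p) { v[runif(length(v)) < p] <- NA; v }
  reports <- data.table::data.table(
    report_id = report_id,
    report_date = format(report_date, "%Y-%m-%d"),
    age_years = mask(as.numeric(age), m$age),
    sex = mask(sex, m$sex),
    country = mask(sample(c("IT", "DE", "US", "GB", "JP", "FR"), n,
                          replace = TRUE), m$country),
    reporter_type = mask(sample(.vs_reporter_types, n, replace = TRUE,
                                prob = c(0.5, 0.2, 0.2, 0.1)), m$reporter_type),
    report_type = mask(sample(.vs_report_types, n, replace = TRUE,
                              prob = c(0.85, 0.1, 0.05)), m$report_type),
    outcome = mask(sample(.vs_outcomes, n, replace = TRUE,
                          prob = c(0.3, 0.2, 0.25, 0.05, 0.2)), m$outcome),
    comment_present = runif(n) < config$p_comment,
    dechallenge = mask(sample(.vs_challenge, n, replace = TRUE,
                              prob = c(0.25, 0.1, 0.35, 0.3)), m$dechallenge),
    rechallenge = mask(sample(.vs_challenge, n, replace = TRUE,
                              prob = c(0.05, 0.05, 0.6, 0.3)), m$rechallenge))

  icsr_set(reports, dr[, -"row_idx"], rx[, -"row_idx"])
}

#' Expected 2x2 cells implied by a generator config
#'
#' Closed-form expectation of the contingency cells the analysis pipeline
#' would count for one (drug, PT) pair in one stratum, obtained by summing
#' the generative probabilities over the discrete age distribution and over
#' presence patterns of all drugs planted for the PT. Exposure follows the
#' analysis definition (drug suspected with its declared route; reports
#' with the drug but route unreported fall in the comparator). Serves as
#' the independent oracle for generator-recovery tests; configs using the
#' `co_occur` knob for this PT are rejected.
#'
#' @param config `generator_config`
#' @param drug drug name (must be configured)
#' @param pt event preferred term (must be configured)
#' @param stratum list with optional `min_age`, `max_age` (age-restricted
#'   strata account for exclusion of missing-age reports)
#' @return list with `E_a`, `E_b`, `E_c`, `E_d`
#' @export
expected_cells <- function(config, drug, pt, stratum = list()) {
  stopifnot(inherits(config, "generator_config"))
  j <- match(drug, config$drugs$name)
  k <- match(pt, config$events$pt_name)
  if (is.na(j)) stop("unknown drug: ", drug, call. = FALSE)
  if (is.na(k)) stop("unknown event PT: ", pt, call. = FALSE)
  if (!is.null(config$co_occur) &&
      pt %in% unlist(config$co_occur$groups))
    stop("expected_cells does not support co-occurrence groups", call. = FALSE)

  yb <- config$age$young; ob <- config$age$old
  ages <- c(yb[1]:yb[2], ob[1]:ob[2])
  q <- config$age$prop_ge65
  w <- c(rep((1 - q) / (yb[2] - yb[1] + 1), yb[2] - yb[1] + 1),
         rep(q / (ob[2] - ob[1] + 1), ob[2] - ob[1] + 1))

  restricted <- !is.null(stratum$min_age) || !is.null(stratum$max_age)
  if (restricted) {
    lo <- stratum$min_age %||% 0
    hi <- stratum$max_age %||% Inf
    keep <- ages >= lo & ages <= hi
    ages <- ages[keep]; w <- w[keep]
    w <- w * (1 - config$missingness$age)  # missing-age reports are excluded
  }

  planted <- config$planted
  s_drugs <- if (is.null(planted)) character() else
    planted$drug_name[planted$pt_name == pt]
  rrr_of <- function(dn) {
    if (!dn %in% s_drugs) 1 else
      planted$rrr[planted$drug_name == dn & planted$pt_name == pt][1]
  }
  others <- setdiff(s_drugs, drug)

  p_drug_age <- function(dn, a) {
    i <- match(dn, config$drugs$name)
    pmin(1, config$drugs$p_report[i] *
           ifelse(a >= 65, config$drugs$elderly_multiplier[i], 1))
  }

  E <- c(a = 0, b = 0, c = 0, d = 0)
  base_mult <- config$events$age_mult_per_decade[k]
  base_p <- config$events$baseline_p[k]
  unrep <- config$drugs$p_route_unreported[j]

  for (ii in seq_along(ages)) {
    a_age <- ages[ii]
    pe0 <- .event_base_p(base_p, base_mult, a_age)
    pD <- p_drug_age(drug, a_age)

    # enumerate presence patterns of the other planted drugs
    combos <- if (length(others)) {
      expand.grid(rep(list(c(FALSE, TRUE)), length(others)))
    } else data.frame(row.names = 1)
    for (ci in seq_len(nrow(combos))) {
      pr <- 1; mult <- 1
      for (oi in seq_along(others)) {
        po <- p_drug_age(others[oi], a_age)
        if (isTRUE(combos[ci, oi])) { pr <- pr * po; mult <- mult * rrr_of(others[oi]) }
        else pr <- pr * (1 - po)
      }
      pe_noD <- min(1, pe0 * mult)
      pe_D <- min(1, pe0 * mult * rrr_of(drug))
      wgt <- w[ii] * pr
      # exposed (drug present, route reported)
      E["a"] <- E["a"] + wgt * pD * (1 - unrep) * pe_D
      E["b"] <- E["b"] + wgt * pD * (1 - unrep) * (1 - pe_D)
      # comparator: drug absent, or present with unreported route
      E["c"] <- E["c"] + wgt * ((1 - pD) * pe_noD + pD * unrep * pe_D)
      E["d"] <- E["d"] + wgt * ((1 - pD) * (1 - pe_noD) + pD * unrep * (1 - pe_D))
    }
  }
  as.list(config$n_reports * E[c("a", "b", "c", "d")]) |>
    stats::setNames(c("E_a", "E_b", "E_c", "E_d"))
}
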