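# Human-readable markdown rendering of a completed screen.

.fmt2 <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.2f", round_half_up(x, 2)))
}

#' Render a markdown summary of a screening run
#'
#' Produces the descriptive surface of a study report: the cohort funnel
#' with standardized two-decimal percentages, per-stratum signal tables
#' with flagged rows in bold and "NA" entries for pairs below the case
#' threshold, and — when signals were flagged — the case-grading summary
#' (median and quartiles of the completeness score, causality category
#' counts, mean +/- SD time-to-onset).
#'
#' @param res `study_results` from [run_screen()]
#' @return character vector of markdown lines
#' @export
run_report <- function(res) {
  stopifnot(inherits(res, "study_results"))
  f <- res$funnel
  out <- c("# Disproportionality screening report", "",
           "## Cohort funnel", "")
  out <- c(out, sprintf("- Reports in database: %d", f$total))
  if (!is.null(f$in_period))
    out <- c(out, sprintf("- In study period: %d (%.2f%%)", f$in_period,
                          pct(f$in_period, f$total)))
  base <- f$in_period %||% f$total
  out <- c(out, sprintf("- Exposed to study drugs (declared route): %d (%.2f%%)",
                        f$exposed, pct(f$exposed, base)))
  for (nm in grep("^exposed_smq_", names(f), value = TRUE)) {
    if (f$exposed > 0)
      out <- c(out, sprintf("  - %s among exposed: %d (%.2f%%)",
                            sub("exposed_smq_", "SMQ ", nm), f[[nm]],
                            pct(f[[nm]], f$exposed)))
  }
  out <- c(out, "", "## Signal screen", "")

  sg <- res$signals
  if (!nrow(sg) || !any(sg$signal %in% TRUE)) {
    out <- c(out, "No signal of disproportionate reporting was found.")
  }
  if (nrow(sg)) {
    for (st in unique(sg$stratum)) {
      out <- c(out, sprintf("### Stratum: %s", st), "",
               "| Drug | Event | N | PRR (95% CI) | ROR (95% CI) | IC (IC025) |",
               "|---|---|---|---|---|---|")
      sub <- sg[stratum == st]
      for (i in seq_len(nrow(sub))) {
        r <- sub[i]
        prr_txt <- if (isTRUE(r$computed))
          sprintf("%s (%s-%s)", .fmt2(r$prr), .fmt2(r$prr_low),
                  .fmt2(r$prr_high)) else "NA"
        ror_txt <- if (isTRUE(r$computed) && !is.na(r$ror))
          sprintf("%s (%s-%s)", .fmt2(r$ror), .fmt2(r$ror_low),
                  .fmt2(r$ror_high)) else "NA"
        ic_txt <- if (isTRUE(r$computed))
          sprintf("%s (%s)", .fmt2(r$ic), .fmt2(r$ic025)) else "NA"
        cells <- c(r$drug,
                   sprintf("%s: %s", toupper(r$event_level), r$event_name),
                   as.character(r$n), prr_txt, ror_txt, ic_txt)
        if (isTRUE(r$signal)) cells <- sprintf("**%s**", cells)
        out <- c(out, paste0("| ", paste(cells, collapse = " | "), " |"))
      }
      out <- c(out, "")
    }
  }

  if (nrow(res$grading)) {
    out <- c(out, "## Case grading (flagged signals only)", "")
    sc <- res$grading$completeness_score
    qs <- quantile(sc, c(0.25, 0.5, 0.75), names = FALSE)
    out <- c(out, sprintf(
      "- Completeness score, median (1st-3rd quartile): %s (%s-%s)",
      .fmt2(qs[2]), .fmt2(qs[1]), .fmt2(qs[3])))
    out <- c(out, sprintf("- Well-documented cases (score > 0.8): %d of %d (%.2f%%)",
                          sum(res$grading$well_documented), nrow(res$grading),
                          pct(sum(res$grading$well_documented),
                              nrow(res$grading))))
    tabc <- sort(table(res$grading$causality_category), decreasing = TRUE)
    for (nm in names(tabc)) {
      out <- c(out, sprintf("- Causality \"%s\": %d (%.2f%%)", nm, tabc[[nm]],
                            pct(tabc[[nm]], nrow(res$grading))))
    }
    for (key in names(res$tto)) {
      t <- res$tto[[key]]
      if (t$n_estimable > 0) {
        out <- c(out, sprintf(
          "- Time to onset [%s]: estimable for %d of %d cases, mean %s +/- %s years",
          key, t$n_estimable, t$n_cases, .fmt2(t$mean_years),
          .fmt2(t$sd_years)))
      } else {
        out <- c(out, sprintf("- Time to onset [%s]: not estimable", key))
      }
    }
  }
  out
}
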