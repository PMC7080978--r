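# Disproportionality estimators: PRR (primary), ROR and IC (confirmatory),
# the >=3-case rule, and signal flagging.
#
# PRR = [a/(a+b)] / [c/(c+d)], with the Wald CI on the log scale
#   exp(ln PRR +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))
# ROR = (a*d)/(b*c), CI exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))
# IC  = log2((a + 0.5)/(E + 0.5)), E = n_drug * n_event / N; the credibility
# lower bound IC025 uses the closed-form shrinkage approximation
#   IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)
# or, optionally, the exact 2.5% quantile of the Gamma(a + 0.5, E + 0.5)
# posterior on the log2 scale.

.z95 <- 1.959964

#' Proportional reporting ratio with Wald interval
#'
#' @param table `contingency_table` (or list with `a`, `b`, `c`, `d`)
#' @param z normal quantile for the interval (default `1.959964`, two-sided
#'   95%)
#' @return list with `prr`, `prr_low`, `prr_high`
#' @export
prr_estimate <- function(table, z = .z95) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  if (a == 0) stop("PRR not computed: no exposed cases (a = 0)", call. = FALSE)
  if (c_ == 0) stop("PRR undefined: event absent from comparator (c = 0)",
                    call. = FALSE)
  prr <- (a / (a + b)) / (c_ / (c_ + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  list(prr = prr, prr_low = prr * exp(-z * se), prr_high = prr * exp(z * se))
}

#' Reporting odds ratio with Wald interval
#'
#' No continuity correction is applied: any zero cell is an error, mirroring
#' the "NA" convention for non-assessable pairs.
#'
#' @inheritParams prr_estimate
#' @return list with `ror`, `ror_low`, `ror_high`
#' @export
ror_estimate <- function(table, z = .z95) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  if (min(a, b, c_, d) == 0)
    stop("ROR undefined: zero cell", call. = FALSE)
  ror <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(ror = ror, ror_low = ror * exp(-z * se), ror_high = ror * exp(z * se))
}

#' Information component with lower credibility bound
#'
#' The +0.5 shrinkage keeps the IC finite for every table, including
#' `a = 0`, and pulls estimates for sparse cells toward zero.
#'
#' @inheritParams prr_estimate
#' @param method `"approx"` for the closed-form IC025 approximation
#'   (deterministic, the default), `"gamma"` for the exact gamma-posterior
#'   quantile
#' @return list with `ic`, `ic025`, `expected` (the expected count E)
#' @export
ic_estimate <- function(table, method = c("approx", "gamma")) {
  method <- match.arg(method)
  a <- table$a
  n <- table$a + table$b + table$c + table$d
  stopifnot(n >= 1)
  e <- (table$a + table$b) * (table$a + table$c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- if (method == "approx") {
    ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  } else {
    log2(qgamma(0.025, shape = a + 0.5, rate = 1) / (e + 0.5))
  }
  list(ic = ic, ic025 = ic025, expected = e)
}

#' Screen contingency tables for signals of disproportionate reporting
#'
#' Applies the three-or-more-cases rule, computes the PRR (primary measure)
#' with its 95% interval, then the ROR and IC as confirmatory measures, and
#' flags a signal when `a >= min_cases` and the PRR lower bound exceeds 1.
#' Pairs below the case threshold, or whose PRR is undefined (event absent
#' from the comparator), are reported with `computed = FALSE` and `NA`
#' estimates, never dropped. A confirmatory measure that is undefined (a
#' zero cell for the ROR) is `NA` without affecting `computed` or the flag.
#'
#' @param tables `contingency_list` or list of `contingency_table`
#' @param min_cases minimum exposed-case count for estimation (default 3)
#' @param z normal quantile for intervals (default `1.959964`)
#' @param ic_method passed to [ic_estimate()]
#' @return `data.table`, one row per table: `drug`, `event_level`,
#'   `event_name`, `stratum`, `a`..`d`, `n`, `expected`, `prr`, `prr_low`,
#'   `prr_high`, `ror`, `ror_low`, `ror_high`, `ic`, `ic025`, `computed`,
#'   `signal`, `reason`
#' @export
screen_signals <- function(tables, min_cases = 3L, z = .z95,
                           ic_method = "approx") {
  rows <- lapply(tables, function(tb) {
    row <- as.data.table.contingency_list(list(tb))
    row[, n := tb$a]
    est <- list(expected = NA_real_, prr = NA_real_, prr_low = NA_real_,
                prr_high = NA_real_, ror = NA_real_, ror_low = NA_real_,
                ror_high = NA_real_, ic = NA_real_, ic025 = NA_real_)
    computed <- FALSE; reason <- NA_character_
    if (tb$a < min_cases) {
      reason <- sprintf("fewer than %d cases", min_cases)
    } else {
      p <- tryCatch(prr_estimate(tb, z), error = function(e) e)
      if (inherits(p, "error")) {
        reason <- conditionMessage(p)
      } else {
        computed <- TRUE
        est[names(p)] <- p
        r <- tryCatch(ror_estimate(tb, z), error = function(e) NULL)
        if (!is.null(r)) est[names(r)] <- r
        i <- ic_estimate(tb, method = ic_method)
        est$ic <- i$ic; est$ic025 <- i$ic025; est$expected <- i$expected
      }
    }
    if (is.na(est$expected)) {
      est$expected <- (tb$a + tb$b) * (tb$a + tb$c) / tb$n_total
    }
    row[, names(est) := est]
    row[, `:=`(computed = computed,
               signal = isTRUE(computed) && tb$a >= min_cases &&
                 est$prr_low > 1,
               reason = reason)]
    row
  })
  data.table::rbindlist(rows)
}

#' Write a screening result table to CSV
#'
#' Full-precision numbers; uncomputed estimates are empty/`NA` cells.
#'
#' @param results output of [screen_signals()]
#' @param path destination CSV
#' @return `path`, invisibly
#' @export
write_signals <- function(results, path) {
  data.table::fwrite(results, path, na = "NA")
  invisible(path)
}
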