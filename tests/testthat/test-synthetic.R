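# Synthetic database generator and its closed-form oracle.

test_that("identical seed and config give identical collections", {
  a <- generate_reports(quick_config(n = 2000, seed = 71, rrr = 3))
  b <- generate_reports(quick_config(n = 2000, seed = 71, rrr = 3))
  expect_identical(a, b)
  c_ <- generate_reports(quick_config(n = 2000, seed = 72, rrr = 3))
  expect_false(identical(a$reports, c_$reports))
})

test_that("config validation rejects bad probabilities and pairs", {
  expect_error(quick_config(p_drug = 1.4), "probabilities")
  expect_error(generator_config(
    10, 1, drugs = data.frame(name = "a", p_report = 0.1),
    events = data.frame(pt_name = "x", baseline_p = 0.1),
    planted = data.frame(drug_name = "a", pt_name = "x", rrr = -1)))
  expect_error(generator_config(
    10, 1, drugs = data.frame(name = "a", p_report = 0.1),
    events = data.frame(pt_name = "Nausea", baseline_p = 0.1)),
    "disjoint")
  # probability cap after multipliers warns
  expect_warning(generate_reports(quick_config(
    n = 500, seed = 3, baseline = 0.6, rrr = 3)), "capped")
})

test_that("expected_cells identities: independence, RRR, linearity", {
  # null config, no age effect: odds identity E_a*E_d = E_b*E_c
  cfg <- quick_config(n = 10000, seed = 1)
  e <- expected_cells(cfg, "ranibizumab", "Parkinson's disease")
  expect_equal(e$E_a * e$E_d, e$E_b * e$E_c, tolerance = 1e-9)
  expect_equal(e$E_a + e$E_b + e$E_c + e$E_d, 10000)

  # planted RRR appears as the expected-cell PRR when exposure/event rare
  cfg3 <- quick_config(n = 1e5, seed = 1, p_drug = 0.002, baseline = 0.001,
                       rrr = 3)
  e3 <- expected_cells(cfg3, "ranibizumab", "Parkinson's disease")
  prr_e <- (e3$E_a / (e3$E_a + e3$E_b)) / (e3$E_c / (e3$E_c + e3$E_d))
  expect_equal(prr_e, 3, tolerance = 0.01)

  # scaling n scales every cell linearly
  e10 <- expected_cells(quick_config(n = 1e6, seed = 1, p_drug = 0.002,
                                     baseline = 0.001, rrr = 3),
                        "ranibizumab", "Parkinson's disease")
  expect_equal(unlist(e10), 10 * unlist(e3), tolerance = 1e-9)

  expect_error(expected_cells(cfg, "nodrug", "Parkinson's disease"), "unknown")
  expect_error(expected_cells(cfg, "ranibizumab", "nopt"), "unknown")
})

test_that("generated cells match expected_cells within 3 binomial SD", {
  dict <- tiny_dict()
  ev <- event_def("pt", "Parkinson's disease")
  for (seed in c(101, 102, 103, 104, 105)) {
    cfg <- quick_config(n = 20000, seed = seed, p_drug = 0.03,
                        baseline = 0.02, age_mult = 1.2, elderly_mult = 2,
                        rrr = 3)
    x <- generate_reports(cfg)
    for (stratum in list(list(), list(min_age = 65))) {
      e <- expected_cells(cfg, "ranibizumab", "Parkinson's disease", stratum)
      cohort <- if (length(stratum)) filter_age(x, 65) else x
      tbl <- build_table(cohort,
                         select_exposed(cohort, "ranibizumab")$reports$report_id,
                         dict, ev)
      obs <- c(tbl$a, tbl$b, tbl$c, tbl$d)
      exp_ <- unlist(e)
      # each of the n generated reports falls in a given cell independently,
      # so the binomial denominator is the full database size
      sd3 <- 3 * sqrt(exp_ * (1 - exp_ / cfg$n_reports))
      expect_true(all(abs(obs - exp_) <= sd3),
                  info = sprintf("seed %d stratum %s: obs (%s) vs exp (%s)",
                                 seed, length(stratum),
                                 paste(obs, collapse = ","),
                                 paste(round(exp_, 1), collapse = ",")))
    }
  }
})

test_that("realized missingness tracks the configured rates within 2%", {
  cfg <- quick_config(n = 100000, seed = 107)
  x <- generate_reports(cfg)
  m <- cfg$missingness
  got <- c(age = mean(is.na(x$reports$age_years)),
           sex = mean(is.na(x$reports$sex)),
           outcome = mean(is.na(x$reports$outcome)),
           start_date = mean(is.na(x$drugs$start_date)),
           onset_date = mean(is.na(x$reactions$onset_date)))
  want <- unlist(m[names(got)])
  expect_true(all(abs(got - want) <= 0.02),
              info = paste(round(got - want, 4), collapse = " "))
})

test_that("null RRR yields PRR near 1 on a moderate database", {
  x <- generate_reports(quick_config(n = 30000, seed = 109, p_drug = 0.1,
                                     baseline = 0.1))
  res <- screen_pair(x)
  expect_lt(abs(res$prr - 1), 0.2)
  expect_false(res$signal)
})

test_that("age confounding: restriction removes the spurious excess", {
  # drug used mainly in the elderly; event rate rises with age; RRR = 1.
  # Rates sized so the elderly stratum holds ~15 expected cases: below the
  # 3-case rule the restricted estimate would be NA rather than near 1.
  cfg <- quick_config(n = 50000, seed = 113, p_drug = 0.004,
                      elderly_mult = 10, baseline = 0.012, age_mult = 2.2)
  x <- generate_reports(cfg)
  all_ages <- screen_pair(x)
  ge65 <- screen_pair(x, stratum = list(min_age = 65))
  expect_gt(all_ages$prr, ge65$prr)
  expect_gt(all_ages$prr, 1.5)          # confounded excess without any RRR
  expect_lt(abs(ge65$prr - 1), 0.5)     # gone within the stratum
  # the generative model predicts the same ordering
  ea <- expected_cells(cfg, "ranibizumab", "Parkinson's disease")
  eg <- expected_cells(cfg, "ranibizumab", "Parkinson's disease",
                       list(min_age = 65))
  prr_of <- function(e) (e$E_a / (e$E_a + e$E_b)) / (e$E_c / (e$E_c + e$E_d))
  expect_gt(prr_of(ea), prr_of(eg))
})

test_that("co-occurrence knob: SMQ counts diverge from PT sums", {
  base <- list(n_reports = 20000, seed = 127,
               drugs = data.frame(name = "ranibizumab", p_report = 0.05),
               events = data.frame(pt_name = c("Parkinson's disease",
                                               "Hypertonia"),
                                   baseline_p = c(0.01, 0.01)))
  cfg_ind <- do.call(generator_config, base)
  cfg_cor <- do.call(generator_config, c(base, list(
    co_occur = list(groups = list(c("Parkinson's disease", "Hypertonia")),
                    p = 0.9))))
  d <- tiny_dict()
  ev_smq <- event_def("smq", "Parkinson-like events")
  count_smq <- function(cfg) sum(event_matches(generate_reports(cfg), d, ev_smq))
  pt_total <- function(cfg) {
    x <- generate_reports(cfg)
    sum(event_matches(x, d, event_def("pt", "Parkinson's disease"))) +
      sum(event_matches(x, d, event_def("pt", "Hypertonia")))
  }
  # correlated PTs: many more double-coded reports, so the SMQ count falls
  # well below the PT sum; independent PTs nearly saturate it
  expect_lt(count_smq(cfg_cor) / pt_total(cfg_cor), 0.75)
  expect_gt(count_smq(cfg_ind) / pt_total(cfg_ind), 0.95)
  expect_error(expected_cells(cfg_cor, "ranibizumab", "Parkinson's disease"),
               "co-occurrence")
})

test_that("generated collections pass validation and carry sane dates", {
  x <- generate_reports(quick_config(n = 3000, seed = 131))
  expect_silent(validate_icsr_set(x))
  # drug start never postdates the report, onset within 30 d of report
  ok_start <- is.na(x$drugs$start_date) |
    vigisignal:::.date_floor(x$drugs$start_date) <=
      as.Date(x$reports$report_date)[match(x$drugs$report_id,
                                           x$reports$report_id)]
  expect_true(all(ok_start))
})
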