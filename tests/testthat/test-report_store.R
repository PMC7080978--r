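# Data model, readers/writers and cohort filters.

test_that("construction validates the schema invariants", {
  x <- bind_icsrs(mk_icsr("r1"), mk_icsr("r2", age = NA))
  expect_s3_class(x, "icsr_set")
  expect_equal(n_reports(x), 2L)

  expect_error(bind_icsrs(mk_icsr("r1"), mk_icsr("r1")), "duplicate report_id")
  expect_error(bind_icsrs(mk_icsr("r1", age = 150)), "age_years.*r1")
  expect_error(bind_icsrs(mk_icsr("r1", role = "main")), "role")
  expect_error(bind_icsrs(mk_icsr("r1", onset = "2019-01-01")),
               "onset_date after report_date")
  expect_error(bind_icsrs(mk_icsr("r1", drug = "")), "drug_name")
  # partial (year-precision) start dates are accepted
  expect_silent(bind_icsrs(mk_icsr("r1", start = "2011")))
  # a drug record with NA route is normalized to the explicit enum level
  x <- bind_icsrs(mk_icsr("r3", route = NA))
  expect_equal(x$drugs$route, "unreported")
})

test_that("jsonl round-trip is the identity; malformed lines are rejected", {
  x <- bind_icsrs(mk_icsr("r1"), mk_icsr("r2", age = NA, sex = NA),
                  mk_icsr("r3", start = "2012", onset = NA))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_reports(x, f, "jsonl")
  y <- read_reports(f, "jsonl")
  expect_equal(data.frame(y$reports), data.frame(x$reports))
  expect_equal(data.frame(y$drugs), data.frame(x$drugs))
  expect_equal(data.frame(y$reactions), data.frame(x$reactions))

  # malformed line: collected with its line number, others read
  writeLines(c(readLines(f), "{not json"), f)
  expect_warning(z <- read_reports(f, "jsonl"), "line\\(s\\): 4")
  expect_equal(n_reports(z), 3L)
  expect_equal(attr(z, "rejected_lines"), 4L)

  # empty collection round-trips
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_reports(empty_icsr_set(), f2, "jsonl")
  expect_equal(n_reports(read_reports(f2, "jsonl")), 0L)
})

test_that("flat_csv re-nests rows sharing a report_id", {
  # two drug rows and one reaction -> 2 csv rows -> one report, 2 drug records
  a <- mk_icsr("r1")
  a$drugs <- rbind(a$drugs,
                   data.frame(report_id = "r1", drug_name = "aflibercept",
                              role = "suspected", route = "intravitreal",
                              indication = NA, start_date = NA,
                              dose_documented = FALSE))
  x <- bind_icsrs(a)
  f <- withr::local_tempfile(fileext = ".csv")
  write_reports(x, f, "flat_csv")
  expect_equal(nrow(data.table::fread(f)), 2L)
  y <- read_reports(f, "flat_csv")
  expect_equal(n_reports(y), 1L)
  expect_equal(nrow(y$drugs), 2L)
  expect_setequal(y$drugs$drug_name, c("ranibizumab", "aflibercept"))

  # conflicting demographics under one id is an error naming the id
  bad <- data.table::fread(f)
  bad$age_years[2] <- 71
  data.table::fwrite(bad, f)
  expect_error(read_reports(f, "flat_csv"), "conflicting demographics.*r1")
})

test_that("flat_csv round-trip on a generated collection", {
  x <- generate_reports(quick_config(n = 150, seed = 11, p_drug = 0.2,
                                     baseline = 0.1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_reports(x, f, "flat_csv")
  y <- read_reports(f, "flat_csv")
  o <- function(dt, ...) data.frame(dt)[do.call(order, as.list(dt)[c(...)]), ]
  expect_equal(o(y$reports, "report_id"), o(x$reports, "report_id"),
               ignore_attr = TRUE)
  expect_equal(o(y$drugs, "report_id", "drug_name"),
               o(x$drugs, "report_id", "drug_name"), ignore_attr = TRUE)
  expect_equal(o(y$reactions, "report_id", "pt_name"),
               o(x$reactions, "report_id", "pt_name"), ignore_attr = TRUE)
})

test_that("exposure selection honours drug, role and route", {
  x <- bind_icsrs(
    mk_icsr("kept"),                                   # suspected, intravitreal
    mk_icsr("unrep", route = "unreported"),            # route not reported
    mk_icsr("conc", role = "concomitant"),             # concomitant only
    mk_icsr("other", drug = "metformin", route = "oral"),
    mk_icsr("case", drug = "RANIBIZUMAB")              # case-insensitive
  )
  sel <- select_exposed(x, "ranibizumab")
  expect_setequal(sel$reports$report_id, c("kept", "case"))
  # relaxing the role picks up the concomitant record
  expect_setequal(select_exposed(x, "ranibizumab", role = "any")$reports$report_id,
                  c("kept", "case", "conc"))
  expect_error(select_exposed(x, character()), "non-empty")
})

test_that("period filter uses a closed interval on report_date", {
  x <- bind_icsrs(mk_icsr("lo", date = "2010-01-01", onset = "2009-12-01",
                          start = "2009-01-01"),
                  mk_icsr("out", date = "2009-12-31", onset = "2009-12-01",
                          start = "2009-01-01"),
                  mk_icsr("hi", date = "2016-12-31"))
  kept <- filter_period(x, "2010-01-01", "2016-12-31")
  expect_setequal(kept$reports$report_id, c("lo", "hi"))
  expect_error(filter_period(x, "2016-01-01", "2010-01-01"), "start must be")
})

test_that("period filter matches a linear scan on a generated fixture", {
  x <- generate_reports(quick_config(n = 200, seed = 3))
  kept <- filter_period(x, "2012-01-01", "2013-12-31")
  d <- as.Date(x$reports$report_date)
  expect_equal(sort(kept$reports$report_id),
               sort(x$reports$report_id[d >= as.Date("2012-01-01") &
                                          d <= as.Date("2013-12-31")]))
})

test_that("age filter: closed bounds, missing ages excluded", {
  x <- bind_icsrs(mk_icsr("a65", age = 65), mk_icsr("a74", age = 74),
                  mk_icsr("a75", age = 75), mk_icsr("miss", age = NA))
  expect_setequal(filter_age(x, 65)$reports$report_id, c("a65", "a74", "a75"))
  # 65-74 and >=75 partition the >=65 cohort disjointly and exhaustively
  band1 <- filter_age(x, 65, 74)$reports$report_id
  band2 <- filter_age(x, 75)$reports$report_id
  expect_setequal(band1, c("a65", "a74"))
  expect_setequal(band2, "a75")
  expect_length(intersect(band1, band2), 0)
  expect_setequal(c(band1, band2), filter_age(x, 65)$reports$report_id)
})

test_that("filters commute and never invent records", {
  x <- generate_reports(quick_config(n = 500, seed = 5, p_drug = 0.2))
  ab <- filter_age(select_exposed(x, "ranibizumab"), 65)
  ba <- select_exposed(filter_age(x, 65), "ranibizumab")
  expect_setequal(ab$reports$report_id, ba$reports$report_id)
  for (f in list(function(z) filter_age(z, 65),
                 function(z) select_exposed(z, "ranibizumab"),
                 function(z) filter_period(z, "2011-01-01", "2015-12-31"))) {
    expect_true(all(f(x)$reports$report_id %in% x$reports$report_id))
  }
})
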