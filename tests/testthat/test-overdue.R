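test_that("duration normalises to months with the day-substitution rule", {
  expect_equal(normalize_duration(2, 0, 0), 24L)
  expect_equal(normalize_duration(1, 6, 15), 19L)  # days > 0 adds one month
  expect_equal(normalize_duration(0, 0, 1), 1L)
  expect_true(is.na(normalize_duration(0, 0, 0)))  # degenerate, excluded
  expect_equal(normalize_duration(c(2, 1, 0), c(0, 6, 0), c(0, 15, 1)),
               c(24L, 19L, 1L))
})

test_that("delay margins follow the three duration classes", {
  m <- apply_margin(c(24, 30, 25, 60, 61, 1, 72))
  expect_equal(as.character(m$margin_class),
               c("SHORT_2X", "INTERMEDIATE_1_5X", "INTERMEDIATE_1_5X",
                 "INTERMEDIATE_1_5X", "LONG_1X", "SHORT_2X", "LONG_1X"))
  expect_equal(m$adjusted_months, c(48L, 45L, 38L, 90L, 61L, 2L, 72L))
  # fractional-month check: 1.5 x 25 = 37.5 rounds up, and 38 calendar
  # months always lands at or after 37 months + 15 days (half-month carried
  # as days), so the ceiling is the generous direction
  d <- as.Date(c("2016-01-31", "2015-06-01", "2019-02-28"))
  expect_true(all(add_months(d, 38) >= add_months(d, 37) + 15))
})

test_that("adjusted months are monotone within classes with documented jumps", {
  m <- apply_margin(1:120)
  within_class <- split(m$adjusted_months, m$margin_class)
  for (adj in within_class) expect_true(all(diff(adj) >= 0))
  expect_true(all(m$adjusted_months >= 1:120))
  # the 24->25 and 60->61 boundaries step down by design (more generous
  # margins on the shorter side), not silently
  expect_equal(m$adjusted_months[24] - m$adjusted_months[25], 48L - 38L)
  expect_equal(m$adjusted_months[60] - m$adjusted_months[61], 90L - 61L)
})

test_that("calendar-month addition agrees with a day-counting oracle", {
  set.seed(101)
  dates <- as.Date("2012-01-01") + sample(0:4000, 1000, replace = TRUE)
  months <- sample(0:90, 1000, replace = TRUE)
  got <- add_months(dates, months)
  oracle <- as.Date(vapply(seq_len(1000), function(i)
    as.numeric(oracle_add_months(dates[i], months[i])), numeric(1)),
    origin = "1970-01-01")
  expect_equal(got, oracle)
  # end-of-month clamping
  expect_equal(add_months(as.Date("2018-01-31"), 1), as.Date("2018-02-28"))
  expect_equal(add_months(as.Date("2020-01-31"), 1), as.Date("2020-02-29"))
})

test_that("filing-due dates chain enrollment anchor, margin and grace", {
  # 6-month duration -> doubled to 12; +6 months grace from the later
  # enrollment date 2018-01-31 gives 2019-07-31
  r <- records_from(raw_record(first_enrollment_india = "31/01/2018",
                               first_enrollment_global = "15/12/2017",
                               duration_years = "0", duration_months = "6",
                               duration_days = "0"))
  est <- estimate_filing_due(r, as_of = as.Date("2022-01-27"))
  expect_equal(est$overall_first_enrollment, as.Date("2018-01-31"))
  expect_equal(est$adjusted_months, 12L)
  expect_equal(est$estimated_completion, as.Date("2019-01-31"))
  expect_equal(est$filing_due, as.Date("2019-07-31"))
  expect_true(est$overdue)

  # a filing-due date exactly on the reference date is overdue (inclusive)
  expect_true(estimate_filing_due(r, as_of = as.Date("2019-07-31"))$overdue)
  expect_false(estimate_filing_due(r, as_of = as.Date("2019-07-30"))$overdue)

  # duration beyond five years starting 2020 cannot be overdue by early 2022
  r2 <- records_from(raw_record(first_enrollment_india = "01/06/2020",
                                first_enrollment_global = "01/06/2020",
                                duration_years = "6", duration_months = "0",
                                duration_days = "0"))
  expect_false(estimate_filing_due(r2, as_of = as.Date("2022-01-27"))$overdue)

  # degenerate duration and missing enrollment dates are excluded, not counted
  r3 <- records_from(
    raw_record(duration_years = "0", duration_months = "0", duration_days = "0"),
    raw_record(ctri_number = "CTRI/2016/01/000002",
               first_enrollment_global = "Date Missing"))
  est3 <- estimate_filing_due(r3)
  expect_equal(est3$excluded,
               c("degenerate_duration", "missing_enrollment_date"))
  expect_true(all(is.na(est3$overdue)))
})

test_that("overdue counts match a brute-force scan and grow with the reference date", {
  g <- generate_registry(registry_config(n_records = 2500, seed = 41))
  v <- classify_scope(g$records)
  mult <- g$records[v$category == "MULTINATIONAL", , drop = FALSE]
  p <- partition_by_completion(mult)
  nc <- p$not_completed
  expect_gt(nrow(nc), 10)

  # independent scan: recompute each filing date with the day-counting oracle
  as_of <- as.Date("2022-01-27")
  expected <- 0L
  for (i in seq_len(nrow(nc))) {
    anchor <- max(parse_registry_date(nc$first_enrollment_india[i]),
                  parse_registry_date(nc$first_enrollment_global[i]))
    m <- nc$duration_years[i] * 12L + nc$duration_months[i] +
      as.integer(nc$duration_days[i] > 0)
    adj <- if (m <= 24) 2L * m else if (m <= 60) as.integer(ceiling(1.5 * m)) else m
    due <- oracle_add_months(oracle_add_months(anchor, adj), 6L)
    if (due <= as_of) expected <- expected + 1L
  }
  res <- count_overdue(nc, as_of = as_of)
  expect_equal(res$count, expected)
  expect_equal(res$n_input, nrow(nc))

  # monotone in the reference date
  dates <- as.Date(c("2019-01-01", "2020-06-01", "2022-01-27", "2024-01-01"))
  counts <- vapply(dates, function(d) count_overdue(nc, as_of = d)$count,
                   integer(1))
  expect_true(all(diff(counts) >= 0))

  expect_equal(count_overdue(nc[0, , drop = FALSE])$count, 0L)
})
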