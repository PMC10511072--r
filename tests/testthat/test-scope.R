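test_that("status pair verdicts follow the applicability rules", {
  r <- records_from(
    raw_record(recruitment_status_india = "Not Applicable",
               recruitment_status_global = "Not Applicable",
               sample_size_india = "700", total_sample_size = "700"),
    raw_record(ctri_number = "CTRI/2016/01/000002",
               recruitment_status_india = "Completed",
               recruitment_status_global = "Completed"),
    raw_record(ctri_number = "CTRI/2016/01/000003",
               recruitment_status_india = "Suspended"),
    raw_record(ctri_number = "CTRI/2016/01/000004",
               recruitment_status_global = "Terminated"),
    raw_record(ctri_number = "CTRI/2016/01/000005",
               recruitment_status_india = "Open",
               recruitment_status_global = "Not Applicable")
  )
  expect_equal(pair_verdict_status(r),
               c("inconsistent", "multinational", "suspended", "terminated",
                 "indian"))
})

test_that("enrollment-date pair verdicts require real dates on both sides", {
  r <- records_from(
    raw_record(first_enrollment_india = "Date Missing",
               first_enrollment_global = "15/02/2016"),
    raw_record(ctri_number = "CTRI/2016/01/000002",
               first_enrollment_india = "01/04/2016",
               first_enrollment_global = "15/03/2016"),
    raw_record(ctri_number = "CTRI/2016/01/000003",
               first_enrollment_india = "07/08/2015",
               first_enrollment_global = "Date Missing")
  )
  expect_equal(pair_verdict_enrollment_dates(r),
               c("foreign", "multinational", "indian"))
})

test_that("sample-size pair verdicts compare total against the India size", {
  r <- records_from(
    raw_record(total_sample_size = "700", sample_size_india = "700"),
    raw_record(ctri_number = "CTRI/2016/01/000002",
               total_sample_size = "40", sample_size_india = "20"),
    raw_record(ctri_number = "CTRI/2016/01/000003",
               total_sample_size = "100", sample_size_india = "120"),
    raw_record(ctri_number = "CTRI/2016/01/000004",
               total_sample_size = "100", sample_size_india = "0"),
    raw_record(ctri_number = "CTRI/2016/01/000005",
               total_sample_size = "", sample_size_india = "50")
  )
  expect_equal(pair_verdict_sample_sizes(r),
               c("indian", "multinational", "inconsistent", "foreign",
                 "inconsistent"))
})

test_that("the three documented ambiguous records are excluded from both scopes", {
  fx <- generate_worked_fixture()
  v <- classify_scope(fx)
  amb <- v[1:3, ]
  expect_false(any(amb$category %in% c("INDIAN", "MULTINATIONAL")))
  # record 1: equal sizes but statuses Not Applicable and a global-only date
  expect_equal(amb$sizes_verdict[1], "indian")
  expect_equal(amb$status_verdict[1], "inconsistent")
  expect_equal(amb$dates_verdict[1], "foreign")
  expect_equal(as.character(amb$category[1]), "AMBIGUOUS_INDIAN_LIKE")
  # record 2: equal sizes contradicted by a Completed global status + dates
  expect_equal(amb$sizes_verdict[2], "indian")
  expect_equal(amb$status_verdict[2], "multinational")
  expect_equal(as.character(amb$category[2]), "AMBIGUOUS_INDIAN_LIKE")
  # record 3: total > India size but global status/date deny a global arm
  expect_equal(amb$sizes_verdict[3], "multinational")
  expect_equal(amb$status_verdict[3], "indian")
  expect_equal(amb$dates_verdict[3], "indian")
  expect_equal(as.character(amb$category[3]), "AMBIGUOUS_MULTINATIONAL_LIKE")
  # the two clean contrast records classify cleanly
  expect_equal(as.character(v$category[4:5]), c("INDIAN", "MULTINATIONAL"))
})

test_that("classification is exhaustive, exclusive, and demotes on any conflict", {
  g <- generate_registry(registry_config(n_records = 600, seed = 5))
  v <- classify_scope(g$records)
  expect_false(any(is.na(v$category)))
  expect_equal(nrow(v), nrow(g$records))

  # unanimity fuzz: flipping any one field of a multinational record to a
  # conflicting sentinel must demote it out of MULTINATIONAL
  mult <- g$records[v$category == "MULTINATIONAL", , drop = FALSE]
  expect_gt(nrow(mult), 5)
  mutations <- list(
    function(r) { r$recruitment_status_global <- "Not Applicable"; r },
    function(r) { r$recruitment_status_india <- "Not Applicable"; r },
    function(r) { r$first_enrollment_global <- "Date Missing"; r },
    function(r) { r$first_enrollment_india <- "Date Missing"; r },
    function(r) { r$sample_size_india <- r$total_sample_size; r },
    function(r) { r$sample_size_india <- r$total_sample_size + 10L; r }
  )
  for (i in seq_len(min(10, nrow(mult)))) {
    for (mut in mutations) {
      m <- mut(mult[i, , drop = FALSE])
      class(m) <- class(mult)
      expect_false(as.character(classify_scope(m)$category) == "MULTINATIONAL")
    }
  }
})

test_that("an India sample with a Not Applicable India status blocks both scopes", {
  r <- records_from(raw_record(sample_size_india = "50",
                               recruitment_status_india = "Not Applicable"))
  v <- classify_scope(r)
  expect_false(as.character(v$category) %in% c("INDIAN", "MULTINATIONAL"))
})

test_that("classification recovers generator ground truth exactly", {
  g <- generate_registry(registry_config(
    n_records = 1000, seed = 17,
    error_rates = c(india_exceeds_total_final = 0, total_final_zero = 0,
                    status_na_with_india_sample = 0, date_missing_global = 0,
                    completed_sentinel_misuse = 0)))
  v <- classify_scope(g$records)
  truth <- g$truth[match(v$ctri_number, g$truth$ctri_number), ]
  expect_equal(as.character(v$category), truth_scope_category(truth$scope))
})
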