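# Independent oracles used across the suite. These deliberately avoid the
# package's own arithmetic: month addition is done by day-by-day scanning,
# filters by plain loops.

# Day-counting month addition: walk forward one day at a time, counting
# month boundaries, until the 1st of the target month is reached; then land
# on the original day-of-month clamped to the target month's length (also
# found by scanning).
oracle_add_months <- function(date, n) {
  stopifnot(length(date) == 1, length(n) == 1, n >= 0)
  if (n == 0) return(date)
  days <- seq(date + 1, date + n * 31 + 62, by = "day")
  mday <- as.POSIXlt(days)$mday
  firsts <- which(mday == 1L)
  first_target <- days[firsts[n]]          # 1st of the month n boundaries on
  last_day <- mday[firsts[n + 1L] - 1L]    # length of that month, by scan
  first_target + min(as.POSIXlt(date)$mday, last_day) - 1
}

# Brute-force record filter scan
oracle_in_window <- function(records, start, end) {
  kept <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    d <- records$registration_date[i]
    kept[i] <- !is.na(d) && d >= as.Date(start) && d <= as.Date(end)
  }
  kept
}

# Map generator scope labels to classifier categories
truth_scope_category <- function(scope) {
  unname(c(indian = "INDIAN", multinational = "MULTINATIONAL",
           foreign_only = "FOREIGN_ONLY", terminated = "TERMINATED",
           suspended = "SUSPENDED", ambiguous_indian = "AMBIGUOUS_INDIAN_LIKE",
           ambiguous_multinational = "AMBIGUOUS_MULTINATIONAL_LIKE",
           other_discrepancy = "OTHER_DISCREPANCY")[scope])
}

# Minimal raw record constructor for hand-built cases; every argument
# overrides a clean multinational template.
raw_record <- function(...) {
  base <- list(
    ctri_number = "CTRI/2016/01/000001",
    registration_date = "15/01/2016",
    trial_type = "Interventional",
    phase = "Phase 3",
    recruitment_status_india = "Open",
    recruitment_status_global = "Open",
    first_enrollment_india = "01/04/2016",
    first_enrollment_global = "15/03/2016",
    total_sample_size = "200",
    sample_size_india = "50",
    final_enrollment_total = "190",
    final_enrollment_india = "48",
    completion_date_india = "Applicable only for Completed/Terminated trials",
    completion_date_global = "Applicable only for Completed/Terminated trials",
    duration_years = "2", duration_months = "0", duration_days = "0",
    primary_sponsor = "Test Sponsor", sponsor_country = "Sweden"
  )
  over <- list(...)
  base[names(over)] <- over
  as.data.frame(base, stringsAsFactors = FALSE)
}

records_from <- function(...) {
  as_trial_records(do.call(rbind, list(...)))
}
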