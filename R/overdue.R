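MARGIN_CLASSES <- c("SHORT_2X", "INTERMEDIATE_1_5X", "LONG_1X")

#' Normalise an estimated trial duration to whole months
#'
#' The registry stores estimated duration as a (years, months, days) triple.
#' Years convert to 12 months each; a non-zero day component is substituted
#' by one extra month; an all-zero triple is degenerate and yields `NA`
#' (such records are excluded from overdue counting and reported
#' separately).
#'
#' @param years,months,days non-negative integer vectors.
#' @return integer vector of months (`NA` for degenerate durations).
#' @export
#' @examples
#' normalize_duration(2, 0, 0)   # 24
#' normalize_duration(1, 6, 15)  # 19
normalize_duration <- function(years, months, days) {
  stopifnot(all(years >= 0, na.rm = TRUE), all(months >= 0, na.rm = TRUE),
            all(days >= 0, na.rm = TRUE))
  m <- years * 12L + months + as.integer(days > 0)
  m[is.na(years) | is.na(months) | is.na(days)] <- NA_integer_
  m[!is.na(m) & m == 0L] <- NA_integer_
  as.integer(m)
}

#' Apply the duration-dependent delay margin
#'
#' To allow sponsors time for delays before a record is called overdue, the
#' estimated duration is inflated by a class-dependent factor:
#'
#' * up to two years (<= 24 months): doubled (`SHORT_2X`);
#' * two to five years (25–60 months): multiplied by 1.5
#'   (`INTERMEDIATE_1_5X`), fractional months rounded up;
#' * longer than five years (> 60 months): no margin (`LONG_1X`).
#'
#' Exactly 24 months falls in the doubled class and exactly 60 months in the
#' 1.5x class — at each overlap the more generous margin applies, which
#' yields fewer false "overdue" labels. Rounding 1.5x up (38 rather than
#' 37.5 months for a 25-month trial) is generous in the same direction.
#'
#' @param duration_months integer vector of normalised months (>= 1).
#' @return data frame with columns `margin_class` and `adjusted_months`.
#' @export
apply_margin <- function(duration_months) {
  m <- as.integer(duration_months)
  cls <- ifelse(is.na(m), NA_character_,
         ifelse(m <= 24L, "SHORT_2X",
         ifelse(m <= 60L, "INTERMEDIATE_1_5X", "LONG_1X")))
  adj <- ifelse(cls == "SHORT_2X", 2L * m,
         ifelse(cls == "INTERMEDIATE_1_5X", as.integer(ceiling(1.5 * m)), m))
  data.frame(margin_class = factor(cls, levels = MARGIN_CLASSES),
             adjusted_months = as.integer(adj))
}

#' Estimate completion and filing-due dates for not-completed trials
#'
#' For each record: the overall first-enrollment date is the later of the
#' India and global dates; the estimated duration is normalised to months
#' ([normalize_duration()]) and inflated by the delay margin
#' ([apply_margin()]); calendar-month addition (with end-of-month clamping,
#' [add_months()]) gives the estimated completion date; a further 6-month
#' grace yields the filing-due date, by which the registry record ought to
#' have been updated. A record is overdue when its filing-due date is on or
#' before `as_of` (inclusive).
#'
#' Records whose enrollment dates are missing or whose duration is
#' degenerate cannot be estimated; they are returned with an `excluded`
#' reason and do not enter the overdue count.
#'
#' @param records a `trial_records` data frame (the not-completed set).
#' @param as_of reference date (default 2022-01-27).
#' @param grace_months filing grace in months (default 6).
#' @return data frame, one row per record, with the enrollment anchor,
#'   duration, margin class, adjusted months, estimated completion date,
#'   filing-due date, `overdue` flag and `excluded` reason (`NA` when
#'   estimable).
#' @export
estimate_filing_due <- function(records, as_of = as.Date("2022-01-27"),
                                grace_months = 6L) {
  as_of <- as.Date(as_of)
  di <- parse_registry_date(records$first_enrollment_india)
  dg <- parse_registry_date(records$first_enrollment_global)
  anchor <- as.Date(pmax(as.numeric(di), as.numeric(dg)), origin = "1970-01-01")
  dur <- normalize_duration(records$duration_years, records$duration_months,
                            records$duration_days)
  mg <- apply_margin(dur)
  excluded <- rep(NA_character_, nrow(records))
  excluded[is.na(di) | is.na(dg)] <- "missing_enrollment_date"
  excluded[is.na(excluded) & is.na(dur)] <- "degenerate_duration"
  est <- add_months(anchor, mg$adjusted_months)
  due <- add_months(est, grace_months)
  ok <- is.na(excluded)
  data.frame(
    ctri_number = records$ctri_number,
    overall_first_enrollment = as.Date(ifelse(ok, anchor, NA), origin = "1970-01-01"),
    duration_months = ifelse(ok, dur, NA_integer_),
    margin_class = ifelse(ok, as.character(mg$margin_class), NA_character_),
    adjusted_months = ifelse(ok, mg$adjusted_months, NA_integer_),
    estimated_completion = as.Date(ifelse(ok, est, NA), origin = "1970-01-01"),
    filing_due = as.Date(ifelse(ok, due, NA), origin = "1970-01-01"),
    overdue = ifelse(ok, due <= as_of, NA),
    excluded = excluded,
    stringsAsFactors = FALSE
  )
}

#' Count overdue not-completed records
#'
#' @param records a `trial_records` data frame (the not-completed set).
#' @param as_of reference date, inclusive.
#' @param grace_months filing grace in months.
#' @return list with `count` (overdue records), `n_estimable`,
#'   `n_input`, `as_of`, and the per-record `table` from
#'   [estimate_filing_due()].
#' @export
count_overdue <- function(records, as_of = as.Date("2022-01-27"),
                          grace_months = 6L) {
  tab <- estimate_filing_due(records, as_of = as_of, grace_months = grace_months)
  list(
    count = sum(tab$overdue, na.rm = TRUE),
    n_estimable = sum(is.na(tab$excluded)),
    n_input = nrow(tab),
    as_of = as.Date(as_of),
    table = tab
  )
}
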