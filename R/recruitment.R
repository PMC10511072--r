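RATIO_CATEGORIES <- c("AT_OR_BELOW_1", "R_101_115", "R_116_160", "R_161_PLUS",
                      "INCORRECT_DATA")
INVALID_TAGS <- c("MISSING", "TOTAL_ZERO", "INDIA_EXCEEDS_TOTAL")

# Shared worker: fraction india/total with validity tags instead of
# exceptions. Invalidity is a finding, never clipped away.
fraction_with_tag <- function(total, india) {
  n <- length(total)
  value <- rep(NA_real_, n)
  tag <- rep("OK", n)
  tag[is.na(total) | is.na(india)] <- "MISSING"
  tag[tag == "OK" & total == 0] <- "TOTAL_ZERO"
  tag[tag == "OK" & india > total] <- "INDIA_EXCEEDS_TOTAL"
  ok <- tag == "OK"
  value[ok] <- india[ok] / total[ok]
  data.frame(value = value, tag = tag, stringsAsFactors = FALSE)
}

#' Planned fraction of recruitment from India
#'
#' *Sample Size from India* / *Total Sample Size*, as registered. When either
#' size is absent the fraction is tagged `MISSING`; a zero total is
#' `TOTAL_ZERO`; an India size exceeding the total is `INDIA_EXCEEDS_TOTAL`.
#' Valid fractions always lie in `[0, 1]`.
#'
#' @param records a `trial_records` data frame.
#' @return data frame with columns `value` (fraction or `NA`) and `tag`.
#' @export
planned_fraction <- function(records) {
  fraction_with_tag(records$total_sample_size, records$sample_size_india)
}

#' Actual fraction of recruitment from India
#'
#' *Final Enrollment numbers achieved (India)* / *(Total)*, with the same
#' validity tags as [planned_fraction()]. The invalid cases (India enrollment
#' exceeding the total, zero totals) are audit findings in their own right
#' and are reported, never corrected.
#'
#' @param records a `trial_records` data frame.
#' @return data frame with columns `value` and `tag`.
#' @export
actual_fraction <- function(records) {
  fraction_with_tag(records$final_enrollment_total,
                    records$final_enrollment_india)
}

#' Flag high recruitment at a cutoff
#'
#' @param fraction numeric vector of recruitment fractions (`NA` = invalid).
#' @param cutoff inclusive threshold (default 0.60: "60% or higher").
#' @return logical vector; `NA` where the fraction is invalid (such records
#'   are excluded from flag counts, not counted as low).
#' @export
flag_high <- function(fraction, cutoff = 0.60) {
  fraction >= cutoff
}

#' Sensitivity sweep of the high-recruitment cutoff
#'
#' Counts flagged trials at the base cutoff and at offsets around it
#' (default 60% +/- 5% and +/- 10%, i.e. cutoffs 0.50, 0.55, 0.60, 0.65,
#' 0.70). Because flagging is a threshold on the same fractions, counts are
#' monotonically non-increasing in the cutoff and the flagged sets are
#' nested.
#'
#' @param fraction numeric vector of fractions (`NA` ignored).
#' @param base_cutoff base cutoff.
#' @param deltas offsets around the base (0 is always included).
#' @return data frame with columns `cutoff` and `n_flagged`.
#' @export
sensitivity_sweep <- function(fraction, base_cutoff = 0.60,
                              deltas = c(-0.10, -0.05, 0.05, 0.10)) {
  cutoffs <- sort(unique(base_cutoff + c(0, deltas)))
  data.frame(
    cutoff = cutoffs,
    n_flagged = vapply(cutoffs,
                       function(k) sum(flag_high(fraction, k), na.rm = TRUE),
                       integer(1))
  )
}

#' Bin the actual-to-planned recruitment ratio
#'
#' The ratio of the *actual* to the *planned* percent recruitment from India,
#' rounded half-up to two decimals and binned into the reporting categories:
#' at or below 1.00; 1.01–1.15; 1.16–1.60; 1.61 and above; or
#' `INCORRECT_DATA` when either fraction is invalid (invalidity is
#' contagious).
#'
#' @param planned,actual data frames from [planned_fraction()] /
#'   [actual_fraction()].
#' @return data frame with columns `ratio` (2-decimal, `NA` when invalid)
#'   and `category` (factor over the five bins).
#' @export
ratio_category <- function(planned, actual) {
  n <- nrow(planned)
  ratio <- rep(NA_real_, n)
  cat_ <- rep("INCORRECT_DATA", n)
  ok <- planned$tag == "OK" & actual$tag == "OK" & planned$value > 0
  ratio[ok] <- round_half_up(actual$value[ok] / planned$value[ok], 2)
  cat_[ok & ratio <= 1.00] <- "AT_OR_BELOW_1"
  cat_[ok & ratio >= 1.01 & ratio <= 1.15] <- "R_101_115"
  cat_[ok & ratio >= 1.16 & ratio <= 1.60] <- "R_116_160"
  cat_[ok & ratio >= 1.61] <- "R_161_PLUS"
  data.frame(ratio = ratio,
             category = factor(cat_, levels = RATIO_CATEGORIES),
             stringsAsFactors = FALSE)
}

#' Per-trial recruitment audit table
#'
#' Combines planned and actual fractions, validity tags, high-recruitment
#' flags at each cutoff, and the ratio bin into one table, one row per
#' trial.
#'
#' @param records a `trial_records` data frame.
#' @param cutoffs numeric vector of cutoffs for the flag columns.
#' @return data frame keyed by `ctri_number`.
#' @export
audit_recruitment <- function(records, cutoffs = c(0.50, 0.55, 0.60, 0.65, 0.70)) {
  pl <- planned_fraction(records)
  ac <- actual_fraction(records)
  rc <- ratio_category(pl, ac)
  out <- data.frame(
    ctri_number = records$ctri_number,
    planned_fraction = pl$value, planned_tag = pl$tag,
    actual_fraction = ac$value, actual_tag = ac$tag,
    ratio = rc$ratio, ratio_category = rc$category,
    stringsAsFactors = FALSE
  )
  for (k in cutoffs) {
    out[[sprintf("planned_high_%02d", round(100 * k))]] <- flag_high(pl$value, k)
    out[[sprintf("actual_high_%02d", round(100 * k))]] <- flag_high(ac$value, k)
  }
  out
}
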