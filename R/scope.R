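SCOPE_CATEGORIES <- c(
  "INDIAN", "MULTINATIONAL", "FOREIGN_ONLY", "TERMINATED", "SUSPENDED",
  "AMBIGUOUS_INDIAN_LIKE", "AMBIGUOUS_MULTINATIONAL_LIKE", "OTHER_DISCREPANCY"
)

norm_status <- function(x) {
  s <- tolower(trimws(ifelse(is.na(x), "", x)))
  s[s %in% c("not applicable", "not applicable (na)", "na")] <- "not applicable"
  s
}

#' Sub-verdict from the recruitment-status field pair
#'
#' Compares *Recruitment Status (India)* with *Recruitment Status (Global)*.
#' A trial can only be multinational if both statuses are present and neither
#' is "Not Applicable"; it is consistent with a purely domestic trial when
#' the India status is applicable and the global one is "Not Applicable" or
#' absent. "Terminated" or "Suspended" in either field produces the
#' corresponding signal, which outranks scope. An applicable global status
#' with an India status of "Not Applicable" signals a trial with no Indian
#' arm (`"foreign"`).
#'
#' @param records a `trial_records` data frame.
#' @return character vector over `{"indian", "multinational", "terminated",
#'   "suspended", "foreign", "inconsistent"}`.
#' @export
pair_verdict_status <- function(records) {
  si <- norm_status(records$recruitment_status_india)
  sg <- norm_status(records$recruitment_status_global)
  i_na <- si == "not applicable"; g_na <- sg == "not applicable"
  i_present <- si != "" & !i_na;  g_present <- sg != "" & !g_na
  v <- rep("inconsistent", length(si))
  v[g_present & i_present] <- "multinational"
  v[i_present & !g_present] <- "indian"
  v[i_na & g_present] <- "foreign"
  v[si == "suspended" | sg == "suspended"] <- "suspended"
  v[si == "terminated" | sg == "terminated"] <- "terminated"
  v
}

#' Sub-verdict from the first-enrollment date pair
#'
#' A multinational trial must carry real dates in both *Date of First
#' Enrollment (India)* and *(Global)*; a domestic trial carries an India date
#' with the global field "Date Missing" or empty; a global date with no
#' India date signals no Indian arm.
#'
#' @param records a `trial_records` data frame.
#' @return character vector over `{"indian", "multinational", "foreign",
#'   "inconsistent"}`.
#' @export
pair_verdict_enrollment_dates <- function(records) {
  ti <- date_field_tag(records$first_enrollment_india)
  tg <- date_field_tag(records$first_enrollment_global)
  absent <- c("DATE_MISSING", "EMPTY", "NOT_APPLICABLE")
  v <- rep("inconsistent", nrow(records))
  v[ti == "DATE" & tg == "DATE"] <- "multinational"
  v[ti == "DATE" & tg %in% absent] <- "indian"
  v[tg == "DATE" & ti %in% absent] <- "foreign"
  v
}

#' Sub-verdict from the sample-size field pair
#'
#' For a multinational trial the *Total Sample Size* must exceed the *Sample
#' Size from India* (with an Indian arm present); equality of the two marks a
#' purely domestic trial; an India size of zero signals no Indian arm; a
#' total below the India size, a zero total, or a missing size is
#' inconsistent.
#'
#' @param records a `trial_records` data frame.
#' @return character vector over `{"indian", "multinational", "foreign",
#'   "inconsistent"}`.
#' @export
pair_verdict_sample_sizes <- function(records) {
  tot <- records$total_sample_size
  ind <- records$sample_size_india
  v <- rep("inconsistent", length(tot))
  ok <- !is.na(tot) & !is.na(ind)
  v[ok & tot > ind & ind > 0] <- "multinational"
  v[ok & tot == ind & ind > 0] <- "indian"
  v[ok & ind == 0 & tot > 0] <- "foreign"
  v
}

#' Classify trial records by scope
#'
#' Applies the three field-pair sub-verdicts ([pair_verdict_status()],
#' [pair_verdict_enrollment_dates()], [pair_verdict_sample_sizes()]) and the
#' unanimity rule: a record is `INDIAN` or `MULTINATIONAL` only if all three
#' pairs agree on that scope. Precedence for everything else, highest first:
#'
#' 1. `TERMINATED` / `SUSPENDED` — either status field says so;
#' 2. `FOREIGN_ONLY` — no Indian arm (India sample size 0, or India status
#'    "Not Applicable" while the global status and enrollment date are
#'    populated);
#' 3. unanimous `INDIAN` / `MULTINATIONAL`;
#' 4. `AMBIGUOUS_INDIAN_LIKE` / `AMBIGUOUS_MULTINATIONAL_LIKE` — the
#'    sample-size pair indicates one scope (sizes equal, or total greater
#'    than the India size) but the other pairs contradict it; when the size
#'    pair is uninformative, agreement of the two remaining pairs decides the
#'    leaning;
#' 5. `OTHER_DISCREPANCY` — residue with no coherent leaning.
#'
#' The sample-size pair anchors the apparent scope of ambiguous records
#' because equality (or excess) of the total over the India sample size is
#' what defines a domestic (or multinational) trial; the remaining pairs act
#' as consistency checks.
#'
#' @param records a `trial_records` data frame (post cohort filtering).
#' @return a data frame: `ctri_number`, the three sub-verdicts, `category`,
#'   and a `rule_fired` audit code.
#' @export
classify_scope <- function(records) {
  vs <- pair_verdict_status(records)
  vd <- pair_verdict_enrollment_dates(records)
  vz <- pair_verdict_sample_sizes(records)

  n <- nrow(records)
  category <- character(n)
  rule <- character(n)

  foreign <- vz == "foreign" | (vs == "foreign" & vd %in% c("foreign", "multinational"))
  lean <- ifelse(vz %in% c("indian", "multinational"), vz,
          ifelse(vs == vd & vs %in% c("indian", "multinational"), vs, "none"))

  for (i in seq_len(n)) {
    if (vs[i] == "terminated") {
      category[i] <- "TERMINATED"; rule[i] <- "status_terminated"
    } else if (vs[i] == "suspended") {
      category[i] <- "SUSPENDED"; rule[i] <- "status_suspended"
    } else if (foreign[i]) {
      category[i] <- "FOREIGN_ONLY"; rule[i] <- "no_india_arm"
    } else if (vs[i] == "indian" && vd[i] == "indian" && vz[i] == "indian") {
      category[i] <- "INDIAN"; rule[i] <- "unanimous_indian"
    } else if (vs[i] == "multinational" && vd[i] == "multinational" &&
               vz[i] == "multinational") {
      category[i] <- "MULTINATIONAL"; rule[i] <- "unanimous_multinational"
    } else if (lean[i] == "indian") {
      category[i] <- "AMBIGUOUS_INDIAN_LIKE"
      rule[i] <- sprintf("indian_leaning_conflict(status=%s,dates=%s,sizes=%s)",
                         vs[i], vd[i], vz[i])
    } else if (lean[i] == "multinational") {
      category[i] <- "AMBIGUOUS_MULTINATIONAL_LIKE"
      rule[i] <- sprintf("multinational_leaning_conflict(status=%s,dates=%s,sizes=%s)",
                         vs[i], vd[i], vz[i])
    } else {
      category[i] <- "OTHER_DISCREPANCY"
      rule[i] <- sprintf("no_coherent_scope(status=%s,dates=%s,sizes=%s)",
                         vs[i], vd[i], vz[i])
    }
  }
  data.frame(
    ctri_number = records$ctri_number,
    status_verdict = vs, dates_verdict = vd, sizes_verdict = vz,
    category = factor(category, levels = SCOPE_CATEGORIES),
    rule_fired = rule,
    stringsAsFactors = FALSE
  )
}
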