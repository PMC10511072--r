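#' Default phase-label tokens counted as phase 2 or phase 3
#'
#' Registry phase strings vary ("Phase 2", "Phase 3", "Phase 2/Phase 3",
#' roman-numeral variants); trials are kept when any token on this allow-list
#' occurs in the normalised phase string. The list is an explicit, editable
#' argument of [filter_phase()] so that the cohort definition is auditable.
#'
#' @export
default_phase_tokens <- function() {
  c("phase 2", "phase 3", "phase ii", "phase iii", "phase2", "phase3",
    "phase 2/phase 3", "2/3", "ii/iii")
}

#' Keep records registered inside a date window
#'
#' Both endpoints are inclusive. Records whose registration date is missing
#' are excluded and tallied in the `dropped` attribute with a reason code.
#'
#' @param records a `trial_records` data frame.
#' @param start,end window bounds (`Date` or ISO strings), `start <= end`.
#' @return the kept subset, with attribute `dropped` = named counts.
#' @export
filter_window <- function(records, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  d <- records$registration_date
  keep <- !is.na(d) & d >= start & d <= end
  tally_filter(records, keep,
               ifelse(is.na(d), "registration_date_missing", "out_of_window"))
}

#' Keep interventional trials
#'
#' Matches the trial-type field against "Interventional" after case and
#' whitespace normalisation; empty or missing types are dropped and tallied.
#'
#' @param records a `trial_records` data frame.
#' @return the kept subset, with attribute `dropped` = named counts.
#' @export
filter_interventional <- function(records) {
  ty <- tolower(trimws(ifelse(is.na(records$trial_type), "", records$trial_type)))
  keep <- ty == "interventional"
  tally_filter(records, keep,
               ifelse(ty == "", "trial_type_missing", "not_interventional"))
}

#' Keep phase 2 and phase 3 trials
#'
#' Token-based matching against an explicit allow-list (see
#' [default_phase_tokens()]): the phase string is lower-cased, whitespace is
#' collapsed, and the record is kept if any token occurs as a substring at
#' token boundaries. Combined labels such as "Phase 2/Phase 3" are kept.
#'
#' @param records a `trial_records` data frame.
#' @param tokens character vector of allowed phase tokens.
#' @return the kept subset, with attribute `dropped` = named counts.
#' @export
filter_phase <- function(records, tokens = default_phase_tokens()) {
  ph <- norm_phase(records$phase)
  keep <- vapply(ph, function(p) {
    if (p == "") return(FALSE)
    any(vapply(tokens, function(tk) phase_token_hit(p, tk), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  tally_filter(records, keep,
               ifelse(ph == "", "phase_missing", "phase_not_2_or_3"))
}

norm_phase <- function(x) {
  x <- tolower(trimws(ifelse(is.na(x), "", x)))
  x <- gsub("\\s*/\\s*", "/", x)
  gsub("\\s+", " ", x)
}

phase_token_hit <- function(phase, token) {
  grepl(paste0("(^|[^a-z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", token),
               "($|[^a-z0-9])"), phase, perl = TRUE)
}

tally_filter <- function(records, keep, reason) {
  dropped <- table(reason[!keep])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- attr(records, "rejects")
  attr(out, "dropped") <- as.list(dropped)
  class(out) <- class(records)
  out
}
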