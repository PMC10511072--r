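#' Partition multinational records by completion-date fields
#'
#' Splits a set of multinational trial records into three buckets using
#' *Date of Study Completion (India)* and *(Global)*:
#'
#' * `completed` — both fields carry real dates;
#' * `not_completed` — both fields carry the sentinel
#'   `"Applicable only for Completed/Terminated trials"`;
#' * `mixed` — everything else (one date and one sentinel, missing values,
#'   other sentinels). This residue is surfaced explicitly rather than
#'   silently dropped so the partition always covers the input.
#'
#' @param records a `trial_records` data frame (already classified
#'   multinational).
#' @return an object of class `completion_partition`: a list with elements
#'   `completed`, `not_completed`, `mixed` (each a `trial_records` subset)
#'   and `membership`, a per-record lookup table.
#' @export
partition_by_completion <- function(records) {
  ti <- date_field_tag(records$completion_date_india)
  tg <- date_field_tag(records$completion_date_global)
  grp <- rep("mixed", nrow(records))
  grp[ti == "DATE" & tg == "DATE"] <- "completed"
  grp[ti == "COMPLETED_SENTINEL" & tg == "COMPLETED_SENTINEL"] <- "not_completed"
  pick <- function(g) {
    out <- records[grp == g, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(list(
    completed = pick("completed"),
    not_completed = pick("not_completed"),
    mixed = pick("mixed"),
    membership = data.frame(ctri_number = records$ctri_number,
                            completion_group = grp, stringsAsFactors = FALSE)
  ), class = "completion_partition")
}

#' @export
print.completion_partition <- function(x, ...) {
  cat("Completion partition of", nrow(x$membership), "multinational records\n")
  cat("  completed:    ", nrow(x$completed), "\n")
  cat("  not completed:", nrow(x$not_completed), "\n")
  cat("  mixed:        ", nrow(x$mixed), "\n")
  invisible(x)
}
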