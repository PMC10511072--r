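#' Run the full registry audit
#'
#' The single entry point of the package. Takes a registry snapshot — a
#' `trial_records` data frame or a path readable by [read_records()] — and
#' runs the whole pipeline:
#'
#' 1. cohort cascade: registration window, interventional type, phase 2/3;
#' 2. scope classification of the phase-2/3 cohort ([classify_scope()]);
#' 3. completion partition of the multinational records
#'    ([partition_by_completion()]);
#' 4. recruitment audit of the completed set (planned and actual fractions,
#'    high-recruitment flags with a cutoff sensitivity sweep, actual:planned
#'    ratio bins) and of the not-completed set (planned fractions);
#' 5. overdue detection on the not-completed set ([count_overdue()]).
#'
#' @param records a `trial_records` data frame, or a path to an SQLite/CSV
#'   snapshot.
#' @param start,end registration window (inclusive).
#' @param cutoff base high-recruitment cutoff (inclusive).
#' @param deltas sensitivity offsets around the cutoff.
#' @param as_of reference date for overdue detection (inclusive).
#' @param grace_months filing grace in months.
#' @param phase_tokens phase allow-list, see [default_phase_tokens()].
#' @param ... passed to [read_records()] when `records` is a path.
#' @return an object of class `ctri_audit`; see [print.ctri_audit()] and
#'   [summary.ctri_audit()]. Per-trial tables live in `$verdicts`,
#'   `$completed_audit`, `$not_completed_audit` and `$overdue$table`.
#' @export
ctri_audit <- function(records,
                       start = as.Date("2013-01-01"),
                       end = as.Date("2020-12-31"),
                       cutoff = 0.60,
                       deltas = c(-0.10, -0.05, 0.05, 0.10),
                       as_of = as.Date("2022-01-27"),
                       grace_months = 6L,
                       phase_tokens = default_phase_tokens(),
                       ...) {
  input_path <- NA_character_
  if (is.character(records) && length(records) == 1) {
    input_path <- records
    records <- read_records(records, ...)
  }
  cutoffs <- sort(unique(cutoff + c(0, deltas)))

  in_window <- filter_window(records, start, end)
  interventional <- filter_interventional(in_window)
  phase23 <- filter_phase(interventional, tokens = phase_tokens)

  verdicts <- classify_scope(phase23)
  scope_counts <- table(verdicts$category)
  multinational <- phase23[verdicts$category == "MULTINATIONAL", , drop = FALSE]
  class(multinational) <- class(phase23)

  part <- partition_by_completion(multinational)

  completed_audit <- audit_recruitment(part$completed, cutoffs = cutoffs)
  not_completed_audit <- audit_recruitment(part$not_completed, cutoffs = cutoffs)

  planned_sweep_completed <-
    sensitivity_sweep(completed_audit$planned_fraction, cutoff, deltas)
  actual_sweep_completed <-
    sensitivity_sweep(completed_audit$actual_fraction, cutoff, deltas)
  planned_sweep_not_completed <-
    sensitivity_sweep(not_completed_audit$planned_fraction, cutoff, deltas)

  ratio_cat <- completed_audit$ratio_category
  ratio_table <- table(ratio_cat)
  invalid_data <- completed_audit[completed_audit$actual_tag %in% INVALID_TAGS |
                                    completed_audit$planned_tag %in% INVALID_TAGS,
                                  c("ctri_number", "planned_tag", "actual_tag")]
  rownames(invalid_data) <- NULL

  overdue <- count_overdue(part$not_completed, as_of = as_of,
                           grace_months = grace_months)

  out <- list(
    cascade = list(
      total = nrow(records),
      in_window = nrow(in_window),
      interventional = nrow(interventional),
      phase23 = nrow(phase23)
    ),
    scope_counts = scope_counts,
    verdicts = verdicts,
    partition = part,
    completion_counts = c(completed = nrow(part$completed),
                          not_completed = nrow(part$not_completed),
                          mixed = nrow(part$mixed)),
    completed_audit = completed_audit,
    not_completed_audit = not_completed_audit,
    sweeps = list(planned_completed = planned_sweep_completed,
                  actual_completed = actual_sweep_completed,
                  planned_not_completed = planned_sweep_not_completed),
    ratio_table = ratio_table,
    invalid_data = invalid_data,
    overdue = overdue,
    provenance = list(
      input = input_path,
      tool = paste0("ctriaudit ", as.character(utils::packageVersion("ctriaudit"))),
      window = c(as.Date(start), as.Date(end)),
      cutoff = cutoff, cutoffs = cutoffs,
      as_of = as.Date(as_of), grace_months = as.integer(grace_months),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  check_report_consistency(out)
  structure(out, class = "ctri_audit")
}

# Internal consistency of the assembled report; run before anything is
# written out.
check_report_consistency <- function(x) {
  cc <- x$cascade
  stopifnot(cc$total >= cc$in_window, cc$in_window >= cc$interventional,
            cc$interventional >= cc$phase23,
            sum(x$scope_counts) == cc$phase23,
            sum(x$completion_counts) == x$scope_counts[["MULTINATIONAL"]],
            x$overdue$n_input == x$completion_counts[["not_completed"]],
            x$overdue$count <= x$overdue$n_estimable)
  invisible(TRUE)
}

#' @export
print.ctri_audit <- function(x, ...) {
  pct <- function(a, b) if (b > 0) sprintf(" (%d%% of %d)", round(100 * a / b), b) else ""
  cc <- x$cascade
  cat("Registry recruitment and reporting audit\n")
  cat(sprintf("  window %s .. %s, cutoff %d%%, reference date %s\n\n",
              x$provenance$window[1], x$provenance$window[2],
              round(100 * x$provenance$cutoff), x$provenance$as_of))
  cat(sprintf("  records read:        %d\n", cc$total))
  cat(sprintf("  in window:           %d\n", cc$in_window))
  cat(sprintf("  interventional:      %d\n", cc$interventional))
  cat(sprintf("  phase 2/3:           %d\n", cc$phase23))
  cat("\n  scope:\n")
  for (nm in names(x$scope_counts))
    cat(sprintf("    %-29s %d\n", nm, x$scope_counts[[nm]]))
  cat("\n  multinational completion: ",
      sprintf("%d completed / %d not completed / %d mixed\n",
              x$completion_counts[["completed"]],
              x$completion_counts[["not_completed"]],
              x$completion_counts[["mixed"]]))
  k <- x$provenance$cutoff
  nhc <- sum(flag_high(x$completed_audit$planned_fraction, k), na.rm = TRUE)
  nac <- sum(flag_high(x$completed_audit$actual_fraction, k), na.rm = TRUE)
  nhn <- sum(flag_high(x$not_completed_audit$planned_fraction, k), na.rm = TRUE)
  nc <- x$completion_counts[["completed"]]
  nn <- x$completion_counts[["not_completed"]]
  cat(sprintf("\n  completed set: %d planned-high%s, %d actual-high%s, %d invalid\n",
              nhc, pct(nhc, nc), nac, pct(nac, nc), nrow(x$invalid_data)))
  cat("  ratio of actual to planned percent recruitment:\n")
  for (nm in names(x$ratio_table))
    cat(sprintf("    %-15s %d\n", nm, x$ratio_table[[nm]]))
  cat(sprintf("\n  not-completed set: %d planned-high%s\n", nhn, pct(nhn, nn)))
  cat(sprintf("  overdue at %s: %d%s (%d estimable)\n",
              x$overdue$as_of, x$overdue$count, pct(x$overdue$count, nn),
              x$overdue$n_estimable))
  invisible(x)
}

#' @export
summary.ctri_audit <- function(object, ...) {
  k <- object$provenance$cutoff
  list(
    cascade = object$cascade,
    scope = as.list(object$scope_counts),
    completion = as.list(object$completion_counts),
    planned_high_completed =
      sum(flag_high(object$completed_audit$planned_fraction, k), na.rm = TRUE),
    actual_high_completed =
      sum(flag_high(object$completed_audit$actual_fraction, k), na.rm = TRUE),
    planned_high_not_completed =
      sum(flag_high(object$not_completed_audit$planned_fraction, k), na.rm = TRUE),
    invalid_data = nrow(object$invalid_data),
    ratio_table = as.list(object$ratio_table),
    overdue = object$overdue[c("count", "n_estimable", "n_input")],
    as_of = object$overdue$as_of
  )
}

#' Serialise an audit report to JSON
#'
#' Counts and per-trial summaries with full numeric precision; percentages
#' are left to the human-readable print method.
#'
#' @param audit a `ctri_audit` object.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(audit, path = NULL) {
  s <- summary(audit)
  s$sweeps <- audit$sweeps
  s$invalid_records <- audit$invalid_data
  s$provenance <- audit$provenance[c("input", "tool", "cutoff", "as_of",
                                     "grace_months", "timestamp")]
  js <- jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", Date = "ISO8601")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write the per-trial audit tables
#'
#' Emits the scope verdicts (with completion-group membership), the
#' completed- and not-completed-set recruitment audits and the per-record
#' completion estimates as CSV files, plus the summary JSON, into a
#' directory.
#'
#' @param audit a `ctri_audit` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_audit <- function(audit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  verdicts <- merge(audit$verdicts, audit$partition$membership,
                    by = "ctri_number", all.x = TRUE, sort = FALSE)
  utils::write.csv(verdicts, file.path(dir, "scope_verdicts.csv"),
                   row.names = FALSE)
  utils::write.csv(audit$completed_audit,
                   file.path(dir, "completed_recruitment.csv"), row.names = FALSE)
  utils::write.csv(audit$not_completed_audit,
                   file.path(dir, "not_completed_recruitment.csv"),
                   row.names = FALSE)
  utils::write.csv(audit$overdue$table,
                   file.path(dir, "completion_estimates.csv"), row.names = FALSE)
  report_json(audit, file.path(dir, "report.json"))
  invisible(dir)
}
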