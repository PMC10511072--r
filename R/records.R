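# Canonical snake_case column set for a registry snapshot. Date-like fields
# are stored as raw character so that sentinel strings survive verbatim;
# registration_date is required to be a real date and is stored as Date.
REGISTRY_COLUMNS <- c(
  "ctri_number", "registration_date", "trial_type", "phase",
  "recruitment_status_india", "recruitment_status_global",
  "first_enrollment_india", "first_enrollment_global",
  "total_sample_size", "sample_size_india",
  "final_enrollment_total", "final_enrollment_india",
  "completion_date_india", "completion_date_global",
  "duration_years", "duration_months", "duration_days",
  "primary_sponsor", "sponsor_country"
)

COUNT_COLUMNS <- c(
  "total_sample_size", "sample_size_india",
  "final_enrollment_total", "final_enrollment_india",
  "duration_years", "duration_months", "duration_days"
)

SENTINEL_DATE_COLUMNS <- c(
  "first_enrollment_india", "first_enrollment_global",
  "completion_date_india", "completion_date_global"
)

#' Read a registry snapshot from SQLite or CSV
#'
#' Reads one row per trial into the canonical record table. The source may be
#' an SQLite database (the format the registry scrape is deposited in) or a
#' CSV file; the format is inferred from the file extension unless given.
#' Verbose source column labels can be mapped onto the canonical snake_case
#' names with `col_map`, which decouples the audit logic from any particular
#' scrape dialect.
#'
#' Dates are accepted in the registry's `dd/mm/yyyy` dialect or ISO
#' `yyyy-mm-dd` and normalised to ISO on output; the sentinel strings
#' `"Date Missing"`, `"Not Applicable"` and
#' `"Applicable only for Completed/Terminated trials"` are preserved verbatim
#' and kept distinct from empty cells. Counts are parsed leniently (commas
#' and whitespace stripped). Rows that cannot be represented — an unparseable
#' registration date, a non-numeric sample size, a date string that is
#' neither a date nor a known sentinel — are not silently dropped: they are
#' collected into a rejects table, available via [record_rejects()].
#'
#' @param source path to an SQLite database or CSV file.
#' @param table_name table to read when the source is SQLite.
#' @param format `"sqlite"`, `"csv"`, or `NULL` to infer from the extension.
#' @param col_map optional named character vector mapping canonical column
#'   names to the labels used in the source, e.g.
#'   `c(total_sample_size = "Total Sample Size")`.
#' @return a `trial_records` data frame (one row per accepted trial) with the
#'   rejects table attached as an attribute.
#' @seealso [write_records()], [record_rejects()]
#' @export
read_records <- function(source, table_name = "trials", format = NULL,
                         col_map = NULL) {
  if (!file.exists(source)) stop("source does not exist: ", source)
  format <- format %||% infer_format(source)
  raw <- switch(format,
    csv = utils::read.csv(source, colClasses = "character",
                          check.names = FALSE, na.strings = NULL),
    sqlite = {
      con <- DBI::dbConnect(RSQLite::SQLite(), source)
      on.exit(DBI::dbDisconnect(con))
      df <- DBI::dbReadTable(con, table_name)
      df[] <- lapply(df, function(x) ifelse(is.na(x), "", as.character(x)))
      df
    },
    stop("unknown format: ", format)
  )
  if (!is.null(col_map)) {
    hit <- match(unname(col_map), names(raw))
    names(raw)[hit[!is.na(hit)]] <- names(col_map)[!is.na(hit)]
  }
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  as_trial_records(raw[REGISTRY_COLUMNS])
}

#' Coerce a raw character table to canonical trial records
#'
#' Applies the same parsing, normalisation and row-rejection rules as
#' [read_records()] to an in-memory table of raw strings.
#'
#' @param raw data frame of character columns with canonical names.
#' @return a `trial_records` data frame with a `rejects` attribute.
#' @export
as_trial_records <- function(raw) {
  n <- nrow(raw)
  reject_reason <- rep(NA_character_, n)
  note <- function(idx, reason) {
    new <- idx & is.na(reject_reason)
    reject_reason[new] <<- reason
  }

  rec <- raw
  rec[] <- lapply(rec, function(x) trimws(ifelse(is.na(x), "", as.character(x))))

  if (n > 0 && anyDuplicated(rec$ctri_number[rec$ctri_number != ""]))
    note(duplicated(rec$ctri_number) & rec$ctri_number != "", "duplicate ctri_number")
  note(rec$ctri_number == "", "empty ctri_number")

  reg <- parse_registry_date(rec$registration_date)
  note(is.na(reg), "unparseable registration_date")

  for (col in COUNT_COLUMNS) {
    v <- parse_count(rec[[col]])
    bad <- is.na(v) & rec[[col]] != ""
    note(bad, paste0("non-numeric ", col))
    rec[[col]] <- v
  }
  for (col in SENTINEL_DATE_COLUMNS) {
    tag <- date_field_tag(rec[[col]])
    note(tag == "INVALID", paste0("unrecognised value in ", col))
    # normalise real dates to ISO; leave sentinels verbatim, empty -> NA
    d <- parse_registry_date(rec[[col]])
    rec[[col]][tag == "DATE"] <- format(d[tag == "DATE"], "%Y-%m-%d")
    rec[[col]][tag == "EMPTY"] <- NA_character_
  }
  rec$registration_date <- reg
  for (col in c("recruitment_status_india", "recruitment_status_global",
                "primary_sponsor", "sponsor_country", "trial_type", "phase")) {
    rec[[col]][rec[[col]] == ""] <- NA_character_
  }

  keep <- is.na(reject_reason)
  rejects <- data.frame(
    row = which(!keep),
    ctri_number = rec$ctri_number[!keep],
    reason = reject_reason[!keep],
    stringsAsFactors = FALSE
  )
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, rejects = rejects,
            class = c("trial_records", "data.frame"))
}

#' Rows rejected while reading a snapshot
#'
#' @param records a `trial_records` object.
#' @return data frame with columns `row`, `ctri_number`, `reason`.
#' @export
record_rejects <- function(records) {
  attr(records, "rejects") %||%
    data.frame(row = integer(), ctri_number = character(),
               reason = character(), stringsAsFactors = FALSE)
}

#' Write trial records to SQLite or CSV
#'
#' The inverse of [read_records()]: `read_records(write_records(x))`
#' reproduces `x` field for field, including sentinel strings. Dates are
#' serialised as ISO `yyyy-mm-dd`; empty cells stay empty.
#'
#' @param records a `trial_records` data frame.
#' @param dest destination path.
#' @param format `"sqlite"`, `"csv"`, or `NULL` to infer from the extension.
#' @param table_name table name for SQLite output.
#' @export
write_records <- function(records, dest, format = NULL, table_name = "trials") {
  format <- format %||% infer_format(dest)
  out <- as.data.frame(records)
  out$registration_date <- format(out$registration_date, "%Y-%m-%d")
  out[] <- lapply(out, function(x) ifelse(is.na(x), "", as.character(x)))
  switch(format,
    csv = utils::write.csv(out, dest, row.names = FALSE, quote = TRUE,
                           fileEncoding = "UTF-8"),
    sqlite = {
      con <- DBI::dbConnect(RSQLite::SQLite(), dest)
      on.exit(DBI::dbDisconnect(con))
      DBI::dbWriteTable(con, table_name, out, overwrite = TRUE)
    },
    stop("unknown format: ", format)
  )
  invisible(dest)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sqlite", "sqlite3", "db")) "sqlite"
  else if (ext %in% c("csv", "txt")) "csv"
  else stop("cannot infer format from extension: ", path)
}

# Lenient count parsing: strip commas/whitespace; "" -> NA; anything else
# non-numeric or negative -> NA (caller decides whether that rejects the row).
parse_count <- function(x) {
  x <- gsub("[,\\s]", "", ifelse(is.na(x), "", x), perl = TRUE)
  v <- suppressWarnings(as.numeric(x))
  v[!is.na(v) & (v < 0 | v != floor(v))] <- NA
  as.integer(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
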