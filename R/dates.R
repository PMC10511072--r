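# Sentinel strings used by the registry in place of values. These are kept
# verbatim in the canonical record table: an empty cell is *not* the same
# thing as "Date Missing".
SENTINEL_DATE_MISSING <- "Date Missing"
SENTINEL_NOT_APPLICABLE <- "Not Applicable"
SENTINEL_COMPLETED <- "Applicable only for Completed/Terminated trials"

#' Tag a raw registry date field
#'
#' Every raw string stored in a date-typed registry field maps to exactly one
#' tag: a parseable date (`"DATE"`), one of the registry's sentinel strings
#' (`"DATE_MISSING"`, `"NOT_APPLICABLE"`, `"COMPLETED_SENTINEL"`), an empty
#' cell (`"EMPTY"`), or `"INVALID"` for anything else. Sentinel matching is
#' case-insensitive; the raw string itself is never altered.
#'
#' @param x character vector of raw field values.
#' @return character vector of tags, same length as `x`.
#' @export
#' @examples
#' date_field_tag(c("15/02/2016", "Date Missing", "", "garbage"))
date_field_tag <- function(x) {
  x_trim <- trimws(ifelse(is.na(x), "", x))
  low <- tolower(x_trim)
  tag <- rep("INVALID", length(x_trim))
  tag[x_trim == ""] <- "EMPTY"
  tag[low == tolower(SENTINEL_DATE_MISSING)] <- "DATE_MISSING"
  tag[low %in% c(tolower(SENTINEL_NOT_APPLICABLE), "not applicable (na)")] <- "NOT_APPLICABLE"
  tag[low == tolower(SENTINEL_COMPLETED)] <- "COMPLETED_SENTINEL"
  parsed <- parse_registry_date(x_trim)
  tag[!is.na(parsed)] <- "DATE"
  tag
}

#' Parse a registry date string
#'
#' Accepts the registry's `dd/mm/yyyy` dialect and ISO `yyyy-mm-dd`.
#' Parsing is strict: the string must round-trip through the matched format
#' (so "31/02/2016" is rejected, not silently rolled over). Sentinels, empty
#' strings and anything unparseable yield `NA`.
#'
#' @param x character vector.
#' @return a `Date` vector, `NA` where no strict parse exists.
#' @export
parse_registry_date <- function(x) {
  x <- trimws(ifelse(is.na(x), "", x))
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  for (fmt in c("%d/%m/%Y", "%Y-%m-%d")) {
    cand <- as.Date(x, format = fmt)
    ok <- !is.na(cand) & format(cand, fmt) == x & is.na(out)
    # reject two-digit years the format would otherwise zero-pad away
    out[ok] <- cand[ok]
  }
  out
}

#' Format dates in the registry's day-first dialect
#'
#' @param d a `Date` vector.
#' @return character vector `dd/mm/yyyy`, `NA` preserved.
#' @export
format_registry_date <- function(d) {
  format(d, "%d/%m/%Y")
}

#' Calendar-month addition with end-of-month clamping
#'
#' Adds `n` calendar months to each date. When the starting day-of-month does
#' not exist in the target month the day is clamped to the month's last day
#' (31 Jan + 1 month = 28/29 Feb). This is the standard convention used by
#' the completion-date estimator.
#'
#' @param date a `Date` vector.
#' @param n integer vector of months to add (recycled).
#' @return a `Date` vector.
#' @export
#' @examples
#' add_months(as.Date("2018-01-31"), 1)   # 2018-02-28
#' add_months(as.Date("2018-01-31"), 18)  # 2019-07-31
add_months <- function(date, n) {
  stopifnot(inherits(date, "Date"))
  len <- max(length(date), length(n))
  date <- rep_len(date, len)
  n <- rep_len(as.integer(n), len)
  lt <- as.POSIXlt(date)
  y <- lt$year + 1900L
  m0 <- lt$mon + n            # zero-based month index, may overflow
  yy <- y + m0 %/% 12L
  mm <- m0 %% 12L + 1L
  out <- as.Date(rep(NA_integer_, len), origin = "1970-01-01")
  ok <- !is.na(date) & !is.na(n)
  if (any(ok)) {
    day <- pmin(lt$mday[ok], days_in_month(yy[ok], mm[ok]))
    out[ok] <- as.Date(sprintf("%04d-%02d-%02d", yy[ok], mm[ok], day))
  }
  out
}

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  d[month == 2L & leap] <- 29L
  d
}

# Round half away from zero to `digits` decimal places (base round() is
# round-half-even; the ratio bins 1.01-1.15 / 1.16-1.60 presume half-up).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
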