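#' Configuration for the synthetic registry generator
#'
#' Defaults emulate the composition of a CTRI snapshot: the fraction of
#' records registered inside the 2013–2020 audit window, the interventional
#' and phase-2/3 fractions, the scope mix of the phase-2/3 interventional
#' cohort, the completed / not-completed / mixed split of multinational
#' records, a right-skewed planned-recruitment-fraction distribution with
#' about 8% mass at or above 0.60, an actual-to-planned ratio mixture
#' populating every reporting bin, and the documented invalid-data modes
#' (final India enrollment exceeding the total; zero final totals).
#'
#' @param n_records number of records to generate.
#' @param seed integer seed; the same seed and config reproduce the dataset
#'   exactly.
#' @param window registration window for in-window records (length-2 Date).
#' @param p_in_window probability a record is registered inside the window.
#' @param p_interventional probability the trial type is "Interventional".
#' @param p_phase23 probability an interventional trial is phase 2 or 3.
#' @param scope_mix named probabilities over the eight scope categories of
#'   phase-2/3 interventional records (must sum to 1).
#' @param completion_mix named probabilities over
#'   `completed`/`not_completed`/`mixed` for multinational records.
#' @param planned_shape1,planned_shape2 Beta parameters of the planned
#'   India-fraction distribution for multinational records.
#' @param ratio_mix named probabilities over the actual:planned ratio bins
#'   `at_or_below_1`, `r_101_115`, `r_116_160`, `r_161_plus`.
#' @param duration_year_probs probabilities for 0–6 duration years.
#' @param error_rates named per-mode injection probabilities:
#'   `india_exceeds_total_final`, `total_final_zero`,
#'   `status_na_with_india_sample`, `date_missing_global`,
#'   `completed_sentinel_misuse`.
#' @return a list of class `registry_config`.
#' @export
registry_config <- function(
    n_records = 1000L,
    seed = 1L,
    window = as.Date(c("2013-01-01", "2020-12-31")),
    p_in_window = 26889 / 39821,
    p_interventional = 19361 / 26889,
    p_phase23 = 6437 / 19361,
    scope_mix = c(indian = 5580, multinational = 473, foreign_only = 22,
                  terminated = 77, suspended = 1, ambiguous_indian = 256,
                  ambiguous_multinational = 18, other_discrepancy = 10) / 6437,
    completion_mix = c(completed = 62, not_completed = 362, mixed = 49) / 473,
    planned_shape1 = 2, planned_shape2 = 4,
    ratio_mix = c(at_or_below_1 = 45, r_101_115 = 6, r_116_160 = 2,
                  r_161_plus = 5) / 58,
    duration_year_probs = c(0.08, 0.30, 0.27, 0.17, 0.10, 0.05, 0.03),
    error_rates = c(india_exceeds_total_final = 2 / 62,
                    total_final_zero = 2 / 62,
                    status_na_with_india_sample = 0,
                    date_missing_global = 0,
                    completed_sentinel_misuse = 0)) {
  cfg <- list(n_records = as.integer(n_records), seed = as.integer(seed),
              window = as.Date(window), p_in_window = p_in_window,
              p_interventional = p_interventional, p_phase23 = p_phase23,
              scope_mix = scope_mix, completion_mix = completion_mix,
              planned_shape1 = planned_shape1, planned_shape2 = planned_shape2,
              ratio_mix = ratio_mix,
              duration_year_probs = duration_year_probs,
              error_rates = error_rates)
  validate_registry_config(cfg)
  structure(cfg, class = "registry_config")
}

validate_registry_config <- function(cfg) {
  for (nm in c("scope_mix", "completion_mix", "ratio_mix")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(nm, " must be a non-negative probability vector summing to 1")
  }
  needed <- c("indian", "multinational", "foreign_only", "terminated",
              "suspended", "ambiguous_indian", "ambiguous_multinational",
              "other_discrepancy")
  if (!all(needed %in% names(cfg$scope_mix)))
    stop("scope_mix must name all eight scope categories")
  invisible(cfg)
}

#' Generate a synthetic registry snapshot with ground truth
#'
#' Produces a `trial_records` table emulating a registry scrape — the field
#' dialects (dd/mm/yyyy dates, sentinel strings), the cohort composition and
#' the documented error modes — together with a per-record ground-truth
#' table kept strictly alongside (never inside) the records.
#'
#' Records of each scope category are built to satisfy that category's
#' defining field pattern exactly; ambiguous categories replicate one of the
#' three documented contradiction patterns (equal sizes with both statuses
#' "Not Applicable" and a global-only date; equal sizes with both statuses
#' "Completed" and both dates; total exceeding the India size with the
#' global status "Not Applicable" and the global date "Date Missing").
#' Error modes injected on top of clean categories are recorded in the
#' truth table's `error_mode` column.
#'
#' @param config a [registry_config()] object (or arguments passed to it).
#' @return list with `records` (a `trial_records` data frame) and `truth`
#'   (data frame: cohort flags, scope, completion group, realised planned
#'   and actual fractions, duration months, filing-due date, error mode).
#' @export
generate_registry <- function(config = registry_config()) {
  if (!inherits(config, "registry_config")) stop("config must be a registry_config")
  cfg <- config
  n <- cfg$n_records
  set.seed(cfg$seed)

  ## cohort strata
  in_window <- stats::runif(n) < cfg$p_in_window
  reg_date <- random_dates(n, cfg$window[1], cfg$window[2])
  n_out <- sum(!in_window)
  if (n_out) {
    before <- stats::runif(n_out) < 0.5
    lo <- random_dates(n_out, as.Date("2008-01-01"), cfg$window[1] - 1)
    hi <- random_dates(n_out, cfg$window[2] + 1, as.Date("2022-01-27"))
    reg_date[!in_window] <- as.Date(ifelse(before, lo, hi), origin = "1970-01-01")
  }
  trial_type <- ifelse(stats::runif(n) < cfg$p_interventional,
                       "Interventional", "Observational")
  is_p23 <- trial_type == "Interventional" & stats::runif(n) < cfg$p_phase23
  phase <- ifelse(is_p23,
                  sample(c("Phase 2", "Phase 3", "Phase 2/Phase 3"), n,
                         replace = TRUE, prob = c(0.45, 0.45, 0.10)),
                  sample(c("Phase 1", "Phase 4", "N/A"), n, replace = TRUE))

  scope <- sample(names(cfg$scope_mix), n, replace = TRUE, prob = cfg$scope_mix)
  completion <- ifelse(
    scope == "multinational",
    sample(names(cfg$completion_mix), n, replace = TRUE, prob = cfg$completion_mix),
    NA_character_)

  ## sizes and planned fractions
  total <- pmax(10L, as.integer(round(stats::rlnorm(n, log(200), 0.9))))
  p_planned <- stats::rbeta(n, cfg$planned_shape1, cfg$planned_shape2)
  india <- integer(n)

  ## enrollment dates: global/india within a year of registration
  d_glob <- reg_date + sample.int(330L, n, replace = TRUE)
  d_ind <- d_glob + sample.int(120L, n, replace = TRUE)  # India starts later
  swap <- stats::runif(n) < 0.5                          # ... or earlier
  tmp <- d_glob[swap]; d_glob[swap] <- d_ind[swap]; d_ind[swap] <- tmp

  ## estimated duration
  dy <- sample(0:6, n, replace = TRUE, prob = cfg$duration_year_probs)
  dm <- sample(0:11, n, replace = TRUE)
  dd <- ifelse(stats::runif(n) < 0.3, sample.int(28L, n, replace = TRUE), 0L)
  zero <- dy == 0L & dm == 0L & dd == 0L
  dm[zero] <- 6L

  ## field scaffolding (filled per scope category below)
  st_i <- character(n); st_g <- character(n)
  fe_i <- character(n); fe_g <- character(n)
  cd_i <- character(n); cd_g <- character(n)
  fin_tot <- rep(NA_integer_, n); fin_ind <- rep(NA_integer_, n)

  open_status <- function(k) sample(c("Open", "Closed", "Completed"), k, replace = TRUE)
  dmy <- function(d) format_registry_date(d)

  idx <- function(g) which(scope == g)

  i <- idx("indian")
  india[i] <- total[i]
  st_i[i] <- open_status(length(i)); st_g[i] <- SENTINEL_NOT_APPLICABLE
  fe_i[i] <- dmy(d_ind[i]); fe_g[i] <- SENTINEL_DATE_MISSING
  cd_i[i] <- SENTINEL_COMPLETED; cd_g[i] <- SENTINEL_NOT_APPLICABLE

  i <- idx("multinational")
  india[i] <- pmax(1L, pmin(total[i] - 1L, as.integer(round(p_planned[i] * total[i]))))
  st_i[i] <- open_status(length(i)); st_g[i] <- open_status(length(i))
  fe_i[i] <- dmy(d_ind[i]); fe_g[i] <- dmy(d_glob[i])

  i <- idx("foreign_only")
  india[i] <- 0L
  st_i[i] <- SENTINEL_NOT_APPLICABLE; st_g[i] <- open_status(length(i))
  fe_i[i] <- SENTINEL_DATE_MISSING; fe_g[i] <- dmy(d_glob[i])
  cd_i[i] <- SENTINEL_NOT_APPLICABLE; cd_g[i] <- SENTINEL_COMPLETED

  i <- idx("terminated")
  india[i] <- pmax(1L, pmin(total[i] - 1L, as.integer(round(p_planned[i] * total[i]))))
  term_in_india <- stats::runif(length(i)) < 0.5
  st_i[i] <- ifelse(term_in_india, "Terminated", open_status(length(i)))
  st_g[i] <- ifelse(term_in_india, open_status(length(i)), "Terminated")
  fe_i[i] <- dmy(d_ind[i]); fe_g[i] <- dmy(d_glob[i])
  cd_i[i] <- SENTINEL_COMPLETED; cd_g[i] <- SENTINEL_COMPLETED

  i <- idx("suspended")
  india[i] <- pmax(1L, pmin(total[i] - 1L, as.integer(round(p_planned[i] * total[i]))))
  st_i[i] <- "Suspended"; st_g[i] <- open_status(length(i))
  fe_i[i] <- dmy(d_ind[i]); fe_g[i] <- dmy(d_glob[i])
  cd_i[i] <- SENTINEL_COMPLETED; cd_g[i] <- SENTINEL_COMPLETED

  ## ambiguous categories replicate the documented contradiction patterns
  i <- idx("ambiguous_indian")
  if (length(i)) {
    pat <- sample(1:2, length(i), replace = TRUE)
    india[i] <- total[i]
    one <- i[pat == 1]   # equal sizes, both statuses Not Applicable, global-only date
    st_i[one] <- SENTINEL_NOT_APPLICABLE; st_g[one] <- SENTINEL_NOT_APPLICABLE
    fe_i[one] <- SENTINEL_DATE_MISSING; fe_g[one] <- dmy(d_glob[one])
    two <- i[pat == 2]   # equal sizes, both statuses Completed, both dates
    st_i[two] <- "Completed"; st_g[two] <- "Completed"
    fe_i[two] <- dmy(d_ind[two]); fe_g[two] <- dmy(d_glob[two])
    cd_i[i] <- SENTINEL_COMPLETED; cd_g[i] <- SENTINEL_COMPLETED
  }

  i <- idx("ambiguous_multinational")
  if (length(i)) {  # total > india, India Completed, global status NA, global date missing
    india[i] <- pmax(1L, pmin(total[i] - 1L, as.integer(round(0.5 * total[i]))))
    st_i[i] <- "Completed"; st_g[i] <- SENTINEL_NOT_APPLICABLE
    fe_i[i] <- dmy(d_ind[i]); fe_g[i] <- SENTINEL_DATE_MISSING
    cd_i[i] <- SENTINEL_COMPLETED; cd_g[i] <- SENTINEL_COMPLETED
  }

  i <- idx("other_discrepancy")
  if (length(i)) {  # sizes uninformative, remaining pairs pull apart
    india[i] <- NA_integer_; total[i] <- NA_integer_
    st_i[i] <- "Open"; st_g[i] <- SENTINEL_NOT_APPLICABLE        # indian-leaning
    fe_i[i] <- dmy(d_ind[i]); fe_g[i] <- dmy(d_glob[i])          # multinational-leaning
    cd_i[i] <- SENTINEL_COMPLETED; cd_g[i] <- SENTINEL_COMPLETED
  }

  ## completion fields + final enrollment for multinational records
  err <- rep(NA_character_, n)
  ratio_factor <- rep(NA_real_, n)
  i <- idx("multinational")
  if (length(i)) {
    comp <- completion[i]
    ic <- i[comp == "completed"]
    inc <- i[comp == "not_completed"]
    imx <- i[comp == "mixed"]
    end_i <- d_ind[ic] + sample.int(900L, length(ic), replace = TRUE)
    end_g <- end_i + sample(-60:60, length(ic), replace = TRUE)
    cd_i[ic] <- dmy(end_i); cd_g[ic] <- dmy(end_g)
    cd_i[inc] <- SENTINEL_COMPLETED; cd_g[inc] <- SENTINEL_COMPLETED
    half <- stats::runif(length(imx)) < 0.5
    cd_i[imx] <- ifelse(half, dmy(d_ind[imx] + 400), SENTINEL_COMPLETED)
    cd_g[imx] <- ifelse(half, SENTINEL_COMPLETED, "")

    ## actual enrollment only for completed multinational trials
    bins <- sample(names(cfg$ratio_mix), length(ic), replace = TRUE,
                   prob = cfg$ratio_mix)
    f <- numeric(length(ic))
    f[bins == "at_or_below_1"] <- stats::runif(sum(bins == "at_or_below_1"), 0.50, 1.00)
    f[bins == "r_101_115"] <- stats::runif(sum(bins == "r_101_115"), 1.02, 1.14)
    f[bins == "r_116_160"] <- stats::runif(sum(bins == "r_116_160"), 1.17, 1.59)
    f[bins == "r_161_plus"] <- stats::runif(sum(bins == "r_161_plus"), 1.62, 3.00)
    pf <- india[ic] / total[ic]
    af <- pmin(1, pf * f)
    fin_tot[ic] <- pmax(1L, as.integer(round(total[ic] * stats::runif(length(ic), 0.85, 1.05))))
    fin_ind[ic] <- pmax(0L, pmin(fin_tot[ic], as.integer(round(af * fin_tot[ic]))))
    ratio_factor[ic] <- f

    ## documented invalid-data modes among completed multinational records
    r1 <- stats::runif(length(ic))
    e1 <- ic[r1 < cfg$error_rates["india_exceeds_total_final"]]
    fin_ind[e1] <- fin_tot[e1] + sample.int(20L, length(e1), replace = TRUE)
    err[e1] <- "india_exceeds_total_final"
    r2 <- stats::runif(length(ic))
    e2 <- setdiff(ic[r2 < cfg$error_rates["total_final_zero"]], e1)
    fin_tot[e2] <- 0L; fin_ind[e2] <- 0L
    err[e2] <- "total_final_zero"
  }

  ## optional extra error modes injected on clean records
  i <- idx("indian")
  r <- stats::runif(length(i))
  e3 <- i[r < cfg$error_rates["status_na_with_india_sample"]]
  st_i[e3] <- SENTINEL_NOT_APPLICABLE; st_g[e3] <- SENTINEL_NOT_APPLICABLE
  fe_i[e3] <- SENTINEL_DATE_MISSING; fe_g[e3] <- dmy(d_glob[e3])
  err[e3] <- "status_na_with_india_sample"

  i <- idx("multinational")
  r <- stats::runif(length(i))
  e4 <- i[r < cfg$error_rates["date_missing_global"]]
  fe_g[e4] <- SENTINEL_DATE_MISSING
  err[e4] <- "date_missing_global"
  r <- stats::runif(length(i))
  e5 <- setdiff(i[r < cfg$error_rates["completed_sentinel_misuse"] &
                    completion[i] == "completed"], e4)
  cd_i[e5] <- SENTINEL_COMPLETED
  err[e5] <- "completed_sentinel_misuse"

  ctri <- sprintf("CTRI/%s/%06d", format(reg_date, "%Y/%m"), seq_len(n))
  sponsors <- c("Aurobindo Research Ltd", "Zenith Biologics Inc",
                "Meridian Therapeutics AB", "National Medical Institute",
                "Cadence CRO Services", "Horizon Pharma GmbH")
  countries <- c("India", "United States", "Sweden", "Germany", "South Korea", "")
  sp <- sample(seq_along(sponsors), n, replace = TRUE)

  raw <- data.frame(
    ctri_number = ctri,
    registration_date = format_registry_date(reg_date),
    trial_type = trial_type,
    phase = phase,
    recruitment_status_india = st_i,
    recruitment_status_global = st_g,
    first_enrollment_india = fe_i,
    first_enrollment_global = fe_g,
    total_sample_size = ifelse(is.na(total), "", as.character(total)),
    sample_size_india = ifelse(is.na(india), "", as.character(india)),
    final_enrollment_total = ifelse(is.na(fin_tot), "", as.character(fin_tot)),
    final_enrollment_india = ifelse(is.na(fin_ind), "", as.character(fin_ind)),
    completion_date_india = cd_i,
    completion_date_global = cd_g,
    duration_years = as.character(dy),
    duration_months = as.character(dm),
    duration_days = as.character(dd),
    primary_sponsor = sponsors[sp],
    sponsor_country = countries[sp],
    stringsAsFactors = FALSE
  )
  records <- as_trial_records(raw)

  dur_norm <- normalize_duration(dy, dm, dd)
  anchor <- as.Date(pmax(as.numeric(d_ind), as.numeric(d_glob)),
                    origin = "1970-01-01")
  adj <- apply_margin(dur_norm)$adjusted_months
  filing_due <- add_months(add_months(anchor, adj), 6L)

  truth <- data.frame(
    ctri_number = ctri,
    in_window = in_window,
    interventional = trial_type == "Interventional",
    phase23 = is_p23,
    scope = scope,
    completion_group = completion,
    planned_fraction = ifelse(is.na(total) | is.na(india) | total == 0,
                              NA_real_, india / pmax(total, 1L)),
    actual_fraction = ifelse(is.na(fin_tot) | fin_tot == 0 |
                               is.na(fin_ind) | fin_ind > fin_tot,
                             NA_real_, fin_ind / pmax(fin_tot, 1L)),
    ratio_factor = ratio_factor,
    duration_months = dur_norm,
    filing_due = filing_due,
    error_mode = err,
    stringsAsFactors = FALSE
  )
  list(records = records, truth = truth, config = cfg)
}

random_dates <- function(k, from, to) {
  from <- as.Date(from); to <- as.Date(to)
  as.Date(sample.int(as.integer(to - from) + 1L, k, replace = TRUE) - 1L +
            as.integer(from), origin = "1970-01-01")
}
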