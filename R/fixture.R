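#' Worked fixture: three documented ambiguous records plus two clean ones
#'
#' Returns five records: the three published examples of ambiguous registry
#' data (equal sizes with both recruitment statuses "Not Applicable" and a
#' global-only enrollment date; equal sizes with both statuses "Completed"
#' and both dates present; a total exceeding the India size with the global
#' status "Not Applicable" and the global date "Date Missing"), plus one
#' minimal consistent domestic record and one minimal consistent
#' multinational record for contrast. The two clean records and the filler
#' fields the published table does not print (registration date, type,
#' phase, sponsor) are synthetic.
#'
#' @return a `trial_records` data frame of five records.
#' @export
generate_worked_fixture <- function() {
  raw <- data.frame(
    ctri_number = c("CTRI/2013/02/003388", "CTRI/2019/06/019635",
                    "CTRI/2020/06/026230", "CTRI/2016/01/900001",
                    "CTRI/2016/02/900002"),
    registration_date = c("01/02/2013", "01/06/2019", "01/06/2020",
                          "15/01/2016", "15/02/2016"),
    trial_type = "Interventional",
    phase = c("Phase 3", "Phase 2", "Phase 3", "Phase 2", "Phase 3"),
    recruitment_status_india = c("Not Applicable", "Completed", "Completed",
                                 "Open", "Open"),
    recruitment_status_global = c("Not Applicable", "Completed",
                                  "Not Applicable", "Not Applicable", "Open"),
    first_enrollment_india = c("Date Missing", "20/06/2019", "07/08/2015",
                               "01/03/2016", "01/04/2016"),
    first_enrollment_global = c("15/02/2016", "01/08/2019", "Date Missing",
                                "Date Missing", "15/03/2016"),
    total_sample_size = c("700", "588", "40", "100", "200"),
    sample_size_india = c("700", "588", "20", "100", "50"),
    final_enrollment_total = c("", "", "", "", ""),
    final_enrollment_india = c("", "", "", "", ""),
    completion_date_india = SENTINEL_COMPLETED,
    completion_date_global = SENTINEL_COMPLETED,
    duration_years = "2", duration_months = "0", duration_days = "0",
    primary_sponsor = "synthetic fixture sponsor",
    sponsor_country = "",
    stringsAsFactors = FALSE
  )
  as_trial_records(raw)
}
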