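# Cohort construction: incident-case selection with washout, clinical
# history lookbacks, phase outcome flags and post-acute exclusions.

WASHOUT_DAYS <- 1095L     # "previous 3 years", half-open [index - 1095, index)
COMORBIDITY_LOOKBACK_DAYS <- 730L
COMED_LOOKBACK_DAYS <- 180L

#' Select incident AMI index events
#'
#' One index event per eligible patient: the first in-period hospital
#' admission with a main ICD-9-CM diagnosis in the 410 family, or an
#' in-period death from ischemic heart disease (ICD-9 410--414) for
#' patients with no in-period AMI admission (out-of-hospital deaths).
#' Patients with any AMI admission in the 3 years strictly before the index
#' date are excluded (incident-case washout, window half-open so the index
#' admission cannot match itself), as are patients aged outside 18--100 at
#' index. Ties among same-day admissions are broken deterministically by
#' (admission date, hospital id, record order); rows with malformed
#' diagnosis codes are skipped with a warning.
#'
#' @param admissions,deaths,patients Registry tables.
#' @param study_period Length-2 vector (start, end) of dates or ISO strings.
#' @return A data frame of index events: `patient_id`, `index_date`,
#'   `reached_hospital_alive`, `hospital_id`, `stemi`, `admission_date`,
#'   `discharge_date`, `length_of_stay` (the last five `NA` for
#'   out-of-hospital deaths).
#' @export
select_incident_ami <- function(admissions, deaths, patients, study_period) {
  period <- as_date(study_period)
  stopifnot(!anyNA(period), period[2] >= period[1])
  adm <- admissions
  ok_code <- grepl("^[0-9V]", adm$main_dx)
  if (any(!ok_code)) {
    warning(sum(!ok_code), " admission row(s) with malformed diagnosis code skipped")
    adm <- adm[ok_code, , drop = FALSE]
  }
  ami <- adm[startsWith(adm$main_dx, icd9_ami_prefix), , drop = FALSE]

  cand <- ami[ami$admission_date >= period[1] & ami$admission_date <= period[2], ,
              drop = FALSE]
  cand <- cand[order(cand$patient_id, cand$admission_date, cand$hospital_id), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand$patient_id), , drop = FALSE]

  idx <- data.frame(patient_id = cand$patient_id,
                    index_date = cand$admission_date,
                    reached_hospital_alive = rep(TRUE, nrow(cand)),
                    hospital_id = cand$hospital_id,
                    stemi = cand$stemi,
                    admission_date = cand$admission_date,
                    discharge_date = cand$discharge_date,
                    stringsAsFactors = FALSE)

  # out-of-hospital entry: in-period ischemic death, no in-period AMI admission
  d <- deaths[matches_prefix(deaths$cause_icd9, icd9_ischemic_death_prefixes) &
                deaths$death_date >= period[1] & deaths$death_date <= period[2] &
                !(deaths$patient_id %in% idx$patient_id), , drop = FALSE]
  if (nrow(d)) {
    idx <- rbind(idx, data.frame(patient_id = d$patient_id,
                                 index_date = d$death_date,
                                 reached_hospital_alive = FALSE,
                                 hospital_id = NA_character_,
                                 stemi = NA,
                                 admission_date = as.Date(NA),
                                 discharge_date = as.Date(NA),
                                 stringsAsFactors = FALSE))
  }

  # 3-year washout on any AMI admission strictly before the index date
  prior <- ami[ami$patient_id %in% idx$patient_id, , drop = FALSE]
  delta <- as.numeric(idx$index_date[match(prior$patient_id, idx$patient_id)] -
                        prior$admission_date)
  washed <- unique(prior$patient_id[delta > 0 & delta <= WASHOUT_DAYS])
  idx <- idx[!(idx$patient_id %in% washed), , drop = FALSE]

  # age restriction at index
  age <- patients$age[match(idx$patient_id, patients$patient_id)]
  idx <- idx[!is.na(age) & age >= 18 & age <= 100, , drop = FALSE]

  idx$length_of_stay <- as.numeric(idx$discharge_date - idx$admission_date)
  idx <- idx[order(idx$patient_id), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

#' Attach clinical history to index events
#'
#' Sets one flag per chronic condition from any qualifying diagnosis
#' (main or secondary) in a hospitalization during the 2 years before the
#' index event, and one flag per prior-drug group from any qualifying ATC
#' dispensing in the previous 6 months. Both lookback windows are half-open
#' and exclude the index date itself. Diabetes and COPD are carried over
#' from the patient table (case-finding for them is upstream of this
#' package). Missing history simply leaves flags `FALSE`.
#'
#' @param index_events Output of [select_incident_ami()].
#' @param patients,admissions,prescriptions Registry tables.
#' @return The analysis table: index events joined with demographics,
#'   travel time, condition flags and prior-drug flags.
#' @export
attach_history <- function(index_events, patients, admissions, prescriptions) {
  p <- patients[match(index_events$patient_id, patients$patient_id), ,
                drop = FALSE]
  rows <- cbind(index_events,
                p[, c("sex", "age", "age_class", "diabetes", "copd",
                      "travel_time_minutes")])

  idx_of <- function(ids) index_events$index_date[match(ids, index_events$patient_id)]

  adm <- admissions[admissions$patient_id %in% index_events$patient_id, ,
                    drop = FALSE]
  dref <- idx_of(adm$patient_id)
  dd <- as.numeric(dref - adm$admission_date)
  adm <- adm[dd > 0 & dd <= COMORBIDITY_LOOKBACK_DAYS, , drop = FALSE]
  codes <- paste(adm$main_dx, adm$secondary_dx, sep = ";")
  for (cm in names(icd9_comorbidity_codes)) {
    hit <- vapply(strsplit(codes, ";", fixed = TRUE), function(cs) {
      any(matches_prefix(cs, icd9_comorbidity_codes[[cm]]))
    }, logical(1))
    rows[[cm]] <- rows$patient_id %in% unique(adm$patient_id[hit])
  }

  rx <- prescriptions[prescriptions$patient_id %in% index_events$patient_id, ,
                      drop = FALSE]
  dref <- idx_of(rx$patient_id)
  dd <- as.numeric(dref - rx$dispense_date)
  rx <- rx[dd > 0 & dd <= COMED_LOOKBACK_DAYS, , drop = FALSE]
  for (dr in names(atc_comed_codes)) {
    hit <- matches_prefix(rx$atc, atc_comed_codes[[dr]])
    rows[[dr]] <- rows$patient_id %in% unique(rx$patient_id[hit])
  }
  rownames(rows) <- NULL
  rows
}

#' Compute the three chained phase outcomes
#'
#' * `survived_emergency`: the patient reached the hospital alive;
#' * `survived_30d` (STEMI admissions only): no death within 30 days of the
#'   admission date (day 30 inclusive);
#' * `survived_31_365` (rows with a discharge date): no death in days
#'   31--365 counted from discharge (both ends inclusive).
#'
#' Later outcomes are `NA` wherever an earlier phase was not survived or
#' the row is outside the phase's at-risk set.
#'
#' @param rows Analysis table from [attach_history()].
#' @param deaths Registry death table.
#' @return `rows` with `death_date` and the three outcome flags added.
#' @export
phase_outcomes <- function(rows, deaths) {
  rows$death_date <- deaths$death_date[match(rows$patient_id, deaths$patient_id)]
  if (any(!is.na(rows$death_date) & rows$death_date < rows$index_date)) {
    stop("death recorded before the index date: data integrity violation")
  }
  rows$survived_emergency <- rows$reached_hospital_alive

  d_adm <- as.numeric(rows$death_date - rows$admission_date)
  rows$survived_30d <- ifelse(
    rows$survived_emergency & rows$stemi %in% TRUE,
    is.na(d_adm) | d_adm > 30, NA)

  d_dis <- as.numeric(rows$death_date - rows$discharge_date)
  rows$survived_31_365 <- ifelse(
    rows$survived_30d %in% TRUE & !is.na(rows$discharge_date),
    is.na(d_dis) | d_dis < 31 | d_dis > 365, NA)
  rows
}

#' Apply the post-acute exclusion rules
#'
#' Restricted to STEMI 30-day survivors, removes patients who died within
#' 30 days after discharge and patients with a hospital stay longer than 28
#' days (length of stay of 29 days or more); a 28-day stay is retained.
#' These exclusions reduce exposure misclassification in the post-acute
#' drug-therapy phase.
#'
#' @param rows Analysis rows restricted to STEMI 30-day survivors; must
#'   carry `discharge_date`, `length_of_stay` and `death_date`.
#' @return The post-acute analysis set.
#' @export
apply_postacute_exclusions <- function(rows) {
  if (!nrow(rows)) return(rows)
  if (!all(rows$survived_30d %in% TRUE)) {
    stop("post-acute exclusions expect STEMI 30-day survivors only")
  }
  if (anyNA(rows$discharge_date)) {
    stop("rows lacking discharge_date in post-acute exclusion input")
  }
  d_dis <- as.numeric(rows$death_date - rows$discharge_date)
  died_30d_post <- !is.na(d_dis) & d_dis <= 30
  long_stay <- rows$length_of_stay > 28
  rows[!died_30d_post & !long_stay, , drop = FALSE]
}

#' Build the full analysis cohort from a registry bundle
#'
#' Runs incident-case selection, history lookbacks, outcome computation and
#' post-acute exclusions, and returns one analysis row per index event with
#' a `postacute` membership flag (`TRUE`/`FALSE` among STEMI 30-day
#' survivors, `NA` elsewhere). The realized cohort flow (counts per stage)
#' is attached as attribute `"flow"`.
#'
#' @param bundle A `registry_bundle`.
#' @param study_period Optional override of the bundle's configured period.
#' @return The analysis data frame.
#' @export
build_cohort <- function(bundle, study_period = NULL) {
  if (is.null(study_period)) {
    study_period <- c(bundle$config$study_period$start,
                      bundle$config$study_period$end)
  }
  idx <- select_incident_ami(bundle$admissions, bundle$deaths,
                             bundle$patients, study_period)
  rows <- attach_history(idx, bundle$patients, bundle$admissions,
                         bundle$prescriptions)
  rows <- phase_outcomes(rows, bundle$deaths)

  surv30 <- which(rows$survived_30d %in% TRUE)
  kept <- apply_postacute_exclusions(rows[surv30, , drop = FALSE])
  rows$postacute <- NA
  rows$postacute[surv30] <- FALSE
  rows$postacute[match(kept$patient_id, rows$patient_id)] <- TRUE

  attr(rows, "flow") <- cohort_flow(rows)
  rows
}

#' @rdname build_cohort
#' @param rows An analysis table from `build_cohort()`.
#' @export
cohort_flow <- function(rows) {
  list(
    n_index = nrow(rows),
    n_reached_alive = sum(rows$reached_hospital_alive),
    n_stemi = sum(rows$stemi %in% TRUE),
    n_survived_30d = sum(rows$survived_30d %in% TRUE),
    n_postacute = sum(rows$postacute %in% TRUE),
    n_survived_31_365 = sum(rows$postacute %in% TRUE &
                              rows$survived_31_365 %in% TRUE),
    p_reached_alive = mean(rows$reached_hospital_alive),
    p_survived_30d = mean(rows$survived_30d[rows$stemi %in% TRUE] %in% TRUE),
    p_survived_31_365 = mean(rows$survived_31_365[rows$postacute %in% TRUE]
                             %in% TRUE)
  )
}
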