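#' Exposure specification for the three care phases
#'
#' Bundles the tunable definitions of the phase-specific quality-of-care
#' exposures: the travel-time dichotomy threshold (minutes), the four
#' evidence-based (EB) drug classes with their ATC code sets, the length of
#' the post-discharge drug-exposure window, and the quantile convention used
#' for the hospital performance quartile cut points.
#'
#' The four EB classes are antiplatelets (ATC B01AC04, B01AC05, B01AC06),
#' beta-blockers (C07), ACE inhibitors/ARBs (C09) and statins (C10AA).
#' Drug exposure is counted by distinct class, not distinct ATC code.
#'
#' @param travel_threshold_minutes Dichotomy threshold for home-to-hospital
#'   travel time, in minutes. Default 10 (the empirical median).
#' @param drug_window_days Length of the post-discharge exposure window in
#'   days; the window is `(discharge, discharge + drug_window_days]`.
#' @param quartile_type Quantile type passed to [stats::quantile()] for the
#'   hospital performance cut points; default 8 (median-unbiased).
#' @param eb_atc_classes Named list of ATC prefix sets for the 4 EB classes.
#' @return An object of class `mpc_exposure_spec`.
#' @export
exposure_spec <- function(travel_threshold_minutes = 10,
                          drug_window_days = 30,
                          quartile_type = 8,
                          eb_atc_classes = list(
                            antiplatelet = c("B01AC04", "B01AC05", "B01AC06"),
                            betablocker  = "C07",
                            acei_arb     = "C09",
                            statin       = "C10AA"
                          )) {
  stopifnot(travel_threshold_minutes > 0, drug_window_days > 0,
            length(eb_atc_classes) == 4L)
  # class code sets must be pairwise disjoint (on prefix containment)
  prefixes <- unlist(eb_atc_classes, use.names = FALSE)
  for (i in seq_along(prefixes)) {
    for (j in seq_along(prefixes)) {
      if (i != j && startsWith(prefixes[i], prefixes[j])) {
        stop("EB ATC class sets overlap: ", prefixes[i], " vs ", prefixes[j])
      }
    }
  }
  structure(list(travel_threshold_minutes = travel_threshold_minutes,
                 drug_window_days = drug_window_days,
                 quartile_type = quartile_type,
                 eb_atc_classes = eb_atc_classes),
            class = "mpc_exposure_spec")
}

travel_levels <- function(spec) {
  t <- spec$travel_threshold_minutes
  c(paste0("<", t), paste0(">=", t))
}

hosp_levels <- function() c("medium", "high", "low")
drug_levels <- function() c("<=2", "3", "4")

#' Dichotomize home-to-hospital travel time
#'
#' Classifies travel time at the threshold of the exposure specification
#' (default: the 10-minute empirical median). Times strictly below the
#' threshold are the reference ("<10") class; the threshold itself falls in
#' the high (">=10") class.
#'
#' @param minutes Non-negative travel times in minutes.
#' @param spec An [exposure_spec()].
#' @return A factor with levels `c("<10", ">=10")` (for the default threshold).
#' @export
classify_travel_time <- function(minutes, spec = exposure_spec()) {
  if (any(!is.finite(minutes)) || any(minutes < 0)) {
    stop("travel time must be a non-negative finite number of minutes")
  }
  lv <- travel_levels(spec)
  factor(ifelse(minutes < spec$travel_threshold_minutes, lv[1], lv[2]),
         levels = lv)
}

#' Aggregate STEMI admissions into hospital performance profiles
#'
#' Computes, per hospital, the two process indicators that define acute-phase
#' performance: the proportion of STEMI admissions treated with PCI
#' (`p_pci`), and the proportion of reperfusions performed within 12 hours
#' that were executed within 90 minutes door-to-balloon (`p_timely`).
#'
#' @param admissions Admission table restricted to the cohort's index STEMI
#'   admissions (columns `hospital_id`, `pci`, `reperf_12h`,
#'   `door_to_balloon_min`).
#' @return A data frame with one row per hospital: counts and the two
#'   proportions (`NA` where the denominator is zero).
#' @export
build_hospital_profiles <- function(admissions) {
  stopifnot(all(c("hospital_id", "pci", "reperf_12h", "door_to_balloon_min")
                %in% names(admissions)))
  hid <- factor(admissions$hospital_id)
  timely <- admissions$reperf_12h &
    !is.na(admissions$door_to_balloon_min) &
    admissions$door_to_balloon_min <= 90
  prof <- data.frame(
    hospital_id = levels(hid),
    n_stemi = as.integer(tabulate(hid)),
    n_pci_on_stemi = as.integer(tapply(admissions$pci, hid, sum)),
    n_reperfusion_12h = as.integer(tapply(admissions$reperf_12h, hid, sum)),
    n_pci_90min = as.integer(tapply(timely, hid, sum)),
    stringsAsFactors = FALSE
  )
  prof$p_pci <- ifelse(prof$n_stemi > 0, prof$n_pci_on_stemi / prof$n_stemi, NA_real_)
  prof$p_timely <- ifelse(prof$n_reperfusion_12h > 0,
                          prof$n_pci_90min / prof$n_reperfusion_12h, NA_real_)
  prof
}

#' Classify hospitals into performance classes by quartile rule
#'
#' A hospital is "high" performance when both indicators are at or above
#' their 75th-percentile cut point across hospitals, "low" when both are at
#' or below their 25th-percentile cut point, and "medium" otherwise. With a
#' degenerate indicator distribution a hospital can qualify for both
#' extremes; such hospitals are classed medium. Hospitals with an undefined
#' indicator (zero denominator) are excluded from the cut-point computation
#' and classed medium with a warning.
#'
#' @param profiles Output of [build_hospital_profiles()].
#' @param spec An [exposure_spec()]; `spec$quartile_type` selects the
#'   [stats::quantile()] convention for the cut points.
#' @return `profiles` with an added `performance_class` factor
#'   (levels medium/high/low).
#' @export
hospital_performance <- function(profiles, spec = exposure_spec()) {
  ok <- is.finite(profiles$p_pci) & is.finite(profiles$p_timely)
  if (sum(ok) < 4L) stop("need at least 4 hospitals with defined indicators")
  if (any(!ok)) {
    warning(sum(!ok), " hospital(s) with undefined indicators classed medium")
  }
  q <- function(x, p) stats::quantile(x[ok], p, type = spec$quartile_type,
                                      names = FALSE)
  hi <- profiles$p_pci >= q(profiles$p_pci, 0.75) &
    profiles$p_timely >= q(profiles$p_timely, 0.75)
  lo <- profiles$p_pci <= q(profiles$p_pci, 0.25) &
    profiles$p_timely <= q(profiles$p_timely, 0.25)
  cls <- rep("medium", nrow(profiles))
  cls[ok & hi & !lo] <- "high"
  cls[ok & lo & !hi] <- "low"
  profiles$performance_class <- factor(cls, levels = hosp_levels())
  profiles
}

# EB class of each ATC code (NA when the code is in no EB class).
eb_class_of <- function(atc, spec) {
  out <- rep(NA_character_, length(atc))
  for (cl in names(spec$eb_atc_classes)) {
    out[matches_prefix(atc, spec$eb_atc_classes[[cl]])] <- cl
  }
  out
}

#' Post-discharge evidence-based drug regimen class
#'
#' Counts the distinct EB drug classes with at least one dispensing in the
#' 30 days after discharge (window `(discharge, discharge + 30]`, an
#' intention-to-treat exposure) and maps the count to the three regimen
#' classes: 0--2 distinct classes to `"<=2"`, 3 to `"3"`, 4 to `"4"`.
#' Duplicate dispensings, and multiple ATC codes within one class, count
#' once.
#'
#' @param prescriptions Dispensing table (`patient_id`, `atc`,
#'   `dispense_date`).
#' @param discharge_date Named `Date` vector of discharge dates; names are
#'   patient ids.
#' @param spec An [exposure_spec()].
#' @return Factor of regimen classes (levels `<=2`, `3`, `4`), one per
#'   element of `discharge_date`, in the same order.
#' @export
drug_regimen_class <- function(prescriptions, discharge_date,
                               spec = exposure_spec()) {
  stopifnot(!is.null(names(discharge_date)), inherits(discharge_date, "Date"))
  rx <- prescriptions[prescriptions$patient_id %in% names(discharge_date), ,
                      drop = FALSE]
  rx$eb <- eb_class_of(rx$atc, spec)
  rx <- rx[!is.na(rx$eb), , drop = FALSE]
  dd <- discharge_date[rx$patient_id]
  offset <- as.numeric(as_date(rx$dispense_date) - dd)
  rx <- rx[offset > 0 & offset <= spec$drug_window_days, , drop = FALSE]
  n_classes <- integer(length(discharge_date))
  names(n_classes) <- names(discharge_date)
  if (nrow(rx)) {
    cnt <- tapply(rx$eb, rx$patient_id, function(x) length(unique(x)))
    n_classes[names(cnt)] <- as.integer(cnt)
  }
  factor(ifelse(n_classes <= 2, "<=2", as.character(n_classes)),
         levels = drug_levels())
}

#' Enumerate the multicomponent process-of-care scenario lattice
#'
#' The cross product of the three phase exposures (2 travel-time classes x
#' 3 hospital performance classes x 3 drug regimen classes) yields 18
#' scenarios. The best scenario is (travel `<10`, `high` performance, `4`
#' drugs); the worst is (travel `>=10`, `low` performance, `<=2` drugs).
#'
#' @param spec An [exposure_spec()].
#' @return A data frame of 18 rows with columns `travel_class`,
#'   `hosp_class`, `drug_class`, `is_best`, `is_worst`; attributes `best`
#'   and `worst` hold the two designated scenarios as named lists.
#' @export
enumerate_scenarios <- function(spec = exposure_spec()) {
  tl <- travel_levels(spec)
  grid <- expand.grid(travel_class = factor(tl, levels = tl),
                      hosp_class = factor(hosp_levels(), levels = hosp_levels()),
                      drug_class = factor(drug_levels(), levels = drug_levels()),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  best <- list(travel_class = tl[1], hosp_class = "high", drug_class = "4")
  worst <- list(travel_class = tl[2], hosp_class = "low", drug_class = "<=2")
  grid$is_best <- grid$travel_class == best$travel_class &
    grid$hosp_class == best$hosp_class & grid$drug_class == best$drug_class
  grid$is_worst <- grid$travel_class == worst$travel_class &
    grid$hosp_class == worst$hosp_class & grid$drug_class == worst$drug_class
  attr(grid, "best") <- best
  attr(grid, "worst") <- worst
  grid
}

#' @rdname enumerate_scenarios
#' @export
best_scenario <- function(spec = exposure_spec()) attr(enumerate_scenarios(spec), "best")

#' @rdname enumerate_scenarios
#' @export
worst_scenario <- function(spec = exposure_spec()) attr(enumerate_scenarios(spec), "worst")

#' Attach the three phase exposures to an analysis table
#'
#' Adds `travel_class` (all rows), `hosp_class` (rows with an index
#' admission, from the quartile classification of the cohort's STEMI
#' admissions) and `drug_class` (rows in the post-acute analysis set) to a
#' cohort analysis table.
#'
#' @param rows Analysis table from [build_cohort()] /
#'   [apply_postacute_exclusions()].
#' @param bundle The `registry_bundle` the cohort was built from.
#' @param spec An [exposure_spec()].
#' @return `rows` with exposure columns added, plus the classified hospital
#'   profile table as attribute `"hospital_profiles"`.
#' @export
classify_exposures <- function(rows, bundle, spec = exposure_spec()) {
  rows$travel_class <- classify_travel_time(rows$travel_time_minutes, spec)

  stemi_adm <- bundle$admissions[
    bundle$admissions$stemi &
      bundle$admissions$patient_id %in% rows$patient_id[rows$stemi %in% TRUE], ,
    drop = FALSE]
  profiles <- hospital_performance(build_hospital_profiles(stemi_adm), spec)
  rows$hosp_class <- factor(
    profiles$performance_class[match(rows$hospital_id, profiles$hospital_id)],
    levels = hosp_levels())

  idx <- which(rows$postacute %in% TRUE)
  if (length(idx)) {
    dd <- rows$discharge_date[idx]
    names(dd) <- rows$patient_id[idx]
    rows$drug_class <- factor(NA_character_, levels = drug_levels())
    rows$drug_class[idx] <- drug_regimen_class(bundle$prescriptions, dd, spec)
  }
  attr(rows, "hospital_profiles") <- profiles
  rows
}
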