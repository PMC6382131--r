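#' Read and write a registry bundle as CSV tables
#'
#' The five linked tables are written as RFC 4180 CSV files (UTF-8,
#' ISO-8601 dates) named `patients.csv`, `admissions.csv`,
#' `prescriptions.csv`, `deaths.csv` and `hospitals.csv`, with the
#' calibration configuration alongside as `calibration.yaml`.
#'
#' @param bundle A `registry_bundle` from [generate_registry()].
#' @param dir Directory to write to / read from (created if missing).
#' @return `write_registry()` returns `dir` invisibly; `read_registry()`
#'   returns a `registry_bundle`.
#' @export
write_registry <- function(bundle, dir) {
  stopifnot(inherits(bundle, "registry_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (t in registry_table_names()) {
    df <- bundle[[t]]
    for (cl in names(df)) if (inherits(df[[cl]], "Date")) {
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    }
    utils::write.csv(df, file.path(dir, paste0(t, ".csv")), row.names = FALSE,
                     fileEncoding = "UTF-8", na = "")
  }
  write_calibration(bundle$config, file.path(dir, "calibration.yaml"))
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  tabs <- lapply(registry_table_names(), function(t) {
    df <- utils::read.csv(file.path(dir, paste0(t, ".csv")),
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = registry_col_classes(t))
    for (cl in grep("date$", names(df), value = TRUE)) df[[cl]] <- as_date(df[[cl]])
    df
  })
  names(tabs) <- registry_table_names()
  tabs$patients$age_class <- factor(tabs$patients$age_class,
                                    levels = c("<65", "65-74", "75-84", "85+"))
  tabs$patients$sex <- factor(tabs$patients$sex, levels = c("M", "F"))
  cfg_path <- file.path(dir, "calibration.yaml")
  tabs$config <- if (file.exists(cfg_path)) read_calibration(cfg_path) else NULL
  structure(tabs, class = "registry_bundle")
}

registry_table_names <- function() {
  c("patients", "admissions", "prescriptions", "deaths", "hospitals")
}

registry_col_classes <- function(t) {
  switch(t,
    admissions = c(main_dx = "character", secondary_dx = "character"),
    deaths = c(cause_icd9 = "character"),
    NA)
}

#' Validate registry bundle invariants
#'
#' Checks referential integrity (every patient id in admissions,
#' prescriptions and deaths exists in the patient table), date sanity
#' (discharge on or after admission, calendar-valid dates, no admission
#' after death) and at most one death record per patient.
#'
#' @param bundle A `registry_bundle`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_registry <- function(bundle) {
  pids <- bundle$patients$patient_id
  if (anyDuplicated(pids)) stop("duplicate patient_id in patients table")
  for (t in c("admissions", "prescriptions", "deaths")) {
    if (!all(bundle[[t]]$patient_id %in% pids)) {
      stop("unknown patient_id in ", t, " table")
    }
  }
  adm <- bundle$admissions
  if (any(adm$discharge_date < adm$admission_date)) {
    stop("admission with discharge before admission date")
  }
  if (anyDuplicated(bundle$deaths$patient_id)) {
    stop("more than one death record for a patient")
  }
  dd <- bundle$deaths$death_date[match(adm$patient_id, bundle$deaths$patient_id)]
  if (any(!is.na(dd) & adm$admission_date > dd)) {
    stop("admission after death")
  }
  for (t in registry_table_names()) {
    for (cl in grep("date$", names(bundle[[t]]), value = TRUE)) {
      if (anyNA(bundle[[t]][[cl]])) stop("missing/invalid date in ", t, "$", cl)
    }
  }
  invisible(TRUE)
}
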