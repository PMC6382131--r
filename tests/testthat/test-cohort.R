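# hand-built micro-registries for the selection and windowing rules

mk_patients <- function(ids, age = 60) {
  n <- length(ids)
  data.frame(patient_id = ids, sex = factor("M", levels = c("M", "F")),
             age = rep_len(age, n),
             age_class = factor("<65", levels = c("<65", "65-74", "75-84", "85+")),
             diabetes = FALSE, copd = FALSE, travel_time_minutes = 5,
             stringsAsFactors = FALSE)
}

mk_adm <- function(patient_id, date, main_dx, stemi = FALSE, los = 5,
                   hospital_id = "H001", secondary_dx = "") {
  data.frame(patient_id = patient_id, hospital_id = hospital_id,
             admission_date = as.Date(date),
             discharge_date = as.Date(date) + los,
             main_dx = main_dx, secondary_dx = secondary_dx, stemi = stemi,
             pci = FALSE, reperf_12h = FALSE, door_to_balloon_min = NA_real_,
             stringsAsFactors = FALSE)
}

no_deaths <- data.frame(patient_id = character(), death_date = as.Date(character()),
                        cause_icd9 = character(), stringsAsFactors = FALSE)
period <- c("2011-01-01", "2014-12-31")

test_that("incident selection applies the 3-year washout with a half-open window", {
  adm <- rbind(
    mk_adm("A", "2012-05-01", "41071"),  # prior AMI 2010-06-01 -> excluded
    mk_adm("A", "2010-06-01", "41091"),
    mk_adm("B", "2013-06-01", "41001"),  # prior exactly 3 years + 1 day -> kept
    mk_adm("B", as.character(as.Date("2013-06-01") - 1096), "41091", los = 3)
  )
  idx <- select_incident_ami(adm, no_deaths, mk_patients(c("A", "B")), period)
  expect_identical(idx$patient_id, "B")
  expect_identical(idx$index_date, as.Date("2013-06-01"))
  expect_true(idx$reached_hospital_alive)
})

test_that("ischemic death records without admission enter as out-of-hospital events", {
  deaths <- data.frame(patient_id = "C", death_date = as.Date("2013-03-03"),
                       cause_icd9 = "414", stringsAsFactors = FALSE)
  idx <- select_incident_ami(mk_adm("C", "2009-01-01", "41011")[0, ], deaths,
                             mk_patients("C"), period)
  expect_identical(nrow(idx), 1L)
  expect_false(idx$reached_hospital_alive)
  expect_true(is.na(idx$hospital_id))
  expect_true(is.na(idx$discharge_date))
})

test_that("same-day duplicate admissions resolve deterministically, bad codes warn", {
  adm <- rbind(mk_adm("D", "2012-01-01", "41071", hospital_id = "H002"),
               mk_adm("D", "2012-01-01", "41001", hospital_id = "H001"),
               mk_adm("E", "2012-01-01", "??x"))
  expect_warning(
    idx <- select_incident_ami(adm, no_deaths, mk_patients(c("D", "E")), period),
    "malformed")
  expect_identical(idx$hospital_id, "H001")  # hospital id breaks the tie
})

test_that("ages outside 18-100 at index are excluded", {
  adm <- rbind(mk_adm("F", "2012-01-01", "41071"),
               mk_adm("G", "2012-01-01", "41071"))
  idx <- select_incident_ami(adm, no_deaths, mk_patients(c("F", "G"),
                                                         age = c(101, 45)),
                             period)
  expect_identical(idx$patient_id, "G")
})

test_that("history lookbacks use half-open 2-year / 6-month windows", {
  index <- select_incident_ami(mk_adm("H", "2013-06-01", "41071"), no_deaths,
                               mk_patients("H"), period)
  adm_hist <- rbind(
    mk_adm("H", "2013-06-01", "41071"),
    mk_adm("H", as.character(as.Date("2013-06-01") - 540), "428"),   # 18 months
    mk_adm("H", as.character(as.Date("2013-06-01") - 800), "427"))   # too old
  rx <- data.frame(
    patient_id = "H",
    atc = c("C10AA05", "C07AB07"),
    dispense_date = as.Date("2013-06-01") - c(210, 30),  # 7 months / 1 month
    stringsAsFactors = FALSE)
  rows <- attach_history(index, mk_patients("H"), adm_hist, rx)
  expect_true(rows$heart_failure)
  expect_false(rows$arrhythmia)          # outside the 2-year window
  expect_false(rows$pre_statin)          # 7 months ago, outside 6-month window
  expect_true(rows$pre_betablocker)
  # absent history leaves every flag FALSE
  rows0 <- attach_history(index, mk_patients("H"), adm_hist[1, ], rx[0, ])
  expect_false(any(unlist(rows0[c(names(icd9_comorbidity_codes),
                                  names(atc_comed_codes))])))
})

test_that("phase outcomes follow the chained windows", {
  adm <- rbind(mk_adm("I", "2012-01-01", "41071", stemi = TRUE, los = 5),
               mk_adm("J", "2012-01-01", "41071", stemi = TRUE, los = 5),
               mk_adm("K", "2012-01-01", "41071", stemi = TRUE, los = 5))
  deaths <- data.frame(
    patient_id = c("I", "J"),
    death_date = c(as.Date("2012-01-01") + 12,            # day 12 of admission
                   as.Date("2012-01-06") + 200),          # day 200 post discharge
    cause_icd9 = "410", stringsAsFactors = FALSE)
  no_rx <- data.frame(patient_id = character(), atc = character(),
                      dispense_date = as.Date(character()),
                      stringsAsFactors = FALSE)
  rows <- attach_history(
    select_incident_ami(adm, deaths, mk_patients(c("I", "J", "K")), period),
    mk_patients(c("I", "J", "K")), adm, no_rx)
  rows <- phase_outcomes(rows, deaths)
  expect_identical(rows$survived_30d[rows$patient_id == "I"], FALSE)
  expect_identical(rows$survived_30d[rows$patient_id == "J"], TRUE)
  expect_identical(rows$survived_31_365[rows$patient_id == "J"], FALSE)
  expect_identical(rows$survived_31_365[rows$patient_id == "K"], TRUE)
  # death before the index event is a data integrity failure
  bad <- deaths
  bad$death_date[1] <- as.Date("2011-12-31")
  expect_error(phase_outcomes(rows, bad), "integrity")
})

test_that("post-acute exclusions follow the 28-day-stay and 30-day-death rules", {
  adm <- rbind(mk_adm("L", "2012-01-01", "41071", stemi = TRUE, los = 29),
               mk_adm("M", "2012-01-01", "41071", stemi = TRUE, los = 28),
               mk_adm("N", "2012-01-01", "41071", stemi = TRUE, los = 5),
               mk_adm("O", "2012-01-01", "41071", stemi = TRUE, los = 5))
  deaths <- data.frame(
    patient_id = c("N", "O"),
    death_date = as.Date("2012-01-06") + c(30, 31),  # 30 vs 31 days post discharge
    cause_icd9 = "410", stringsAsFactors = FALSE)
  pts <- mk_patients(c("L", "M", "N", "O"))
  rows <- phase_outcomes(
    attach_history(select_incident_ami(adm, deaths, pts, period), pts, adm,
                   data.frame(patient_id = character(), atc = character(),
                              dispense_date = as.Date(character()))),
    deaths)
  kept <- apply_postacute_exclusions(rows[rows$survived_30d %in% TRUE, ])
  expect_setequal(kept$patient_id, c("M", "O"))  # 28-day stay and day-31 death stay in
  expect_identical(kept$survived_31_365[kept$patient_id == "O"], FALSE)
  # missing discharge date violates the contract
  rows2 <- rows[rows$survived_30d %in% TRUE, ]
  rows2$discharge_date[1] <- NA
  expect_error(apply_postacute_exclusions(rows2), "discharge_date")
})

test_that("cohort construction is a subset chain and deterministic", {
  b <- small_bundle()
  rows <- build_cohort(b)
  surv30 <- rows$patient_id[rows$survived_30d %in% TRUE]
  stemi <- rows$patient_id[rows$stemi %in% TRUE]
  alive <- rows$patient_id[rows$reached_hospital_alive]
  post <- rows$patient_id[rows$postacute %in% TRUE]
  expect_true(all(post %in% surv30))
  expect_true(all(surv30 %in% stemi))
  expect_true(all(stemi %in% alive))
  expect_true(all(alive %in% rows$patient_id))
  # prevalent patients planted by the generator are washed out
  expect_false(any(startsWith(rows$patient_id, "X")))
  expect_identical(nrow(rows), b$config$n_patients)
  # re-running the builder reproduces the same table
  expect_identical(build_cohort(b), rows, ignore_attr = TRUE)
})

test_that("the builder recovers the generator's planted history flags", {
  b <- small_bundle()
  rows <- build_cohort(b)
  p <- b$patients[match(rows$patient_id, b$patients$patient_id), ]
  for (fl in c(names(icd9_comorbidity_codes), names(atc_comed_codes))) {
    expect_identical(rows[[fl]], p[[fl]])
  }
  # realized exclusion fractions sit near their configured rates
  n30 <- sum(rows$survived_30d %in% TRUE)
  excl <- n30 - sum(rows$postacute %in% TRUE)
  p_excl <- 1 - (1 - b$config$excl_death30_frac) * (1 - b$config$excl_longstay_frac)
  expect_lt(abs(excl / n30 - p_excl), 3 * sqrt(p_excl * (1 - p_excl) / n30))
})
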