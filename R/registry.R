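# Synthetic health-information-system registry generator.
#
# The generator simulates the three-phase survival process forward:
# covariates -> emergency-phase outcome -> STEMI hospital admission with
# hospital-level performance and random intercept -> 30-day outcome ->
# post-acute exclusions and drug regimen -> 31-365-day outcome; then it
# materializes the process as linked administrative tables (patients,
# admissions, prescriptions, deaths, hospitals) so the cohort-construction
# rules have real records to work on.

# Linear predictor (log-odds contributions, no intercept) for one phase.
# `effects` maps covariate name -> OR (scalar, for logical columns) or a
# named OR vector over non-reference factor levels.
phase_linpred <- function(data, effects) {
  eta <- numeric(nrow(data))
  for (nm in names(effects)) {
    or <- effects[[nm]]
    col <- data[[nm]]
    if (is.null(col)) stop("phase effect refers to missing covariate: ", nm)
    if (length(or) == 1L && is.null(names(or))) {
      eta <- eta + log(or) * as.numeric(col)
    } else {
      b <- log(or)[as.character(col)]
      b[is.na(b)] <- 0
      eta <- eta + b
    }
  }
  eta
}

# Bernoulli flag with marginal prevalence `prev` and a log-odds gradient over
# age classes; the intercept is solved so the marginal stays exact for the
# sampled age distribution.
sample_graded_flag <- function(age_idx, prev, gradient) {
  if (prev <= 0) return(rep(FALSE, length(age_idx)))
  eta <- gradient * (age_idx - 1)
  a <- solve_marginal_intercept(eta, prev, label = "covariate prevalence")
  stats::runif(length(age_idx)) < stats::plogis(a + eta)
}

sample_covariates <- function(cfg, n, spec = exposure_spec()) {
  age_class <- sample_levels(n, cfg$age_class_shares)
  age_idx <- as.integer(age_class)
  lo <- c(cfg$age_bounds[1], 65, 75, 85)
  hi <- c(64, 74, 84, cfg$age_bounds[2])
  age <- floor(stats::runif(n, lo[age_idx], hi[age_idx] + 1))
  cov <- data.frame(
    sex = factor(ifelse(stats::runif(n) < cfg$male_share, "M", "F"),
                 levels = c("M", "F")),
    age = pmin(age, cfg$age_bounds[2]),
    age_class = age_class,
    diabetes = sample_graded_flag(age_idx, cfg$diabetes_prev,
                                  cfg$comorbidity_age_gradient),
    copd = sample_graded_flag(age_idx, cfg$copd_prev,
                              cfg$comorbidity_age_gradient),
    stringsAsFactors = FALSE
  )
  for (cm in names(cfg$comorbidity_prevs)) {
    cov[[cm]] <- sample_graded_flag(age_idx, cfg$comorbidity_prevs[[cm]],
                                    cfg$comorbidity_age_gradient)
  }
  for (dr in names(cfg$comed_prevs)) {
    cov[[dr]] <- sample_graded_flag(age_idx, cfg$comed_prevs[[dr]],
                                    cfg$comorbidity_age_gradient)
  }
  tt <- cfg$travel_time_distribution
  mu <- log(tt$threshold_minutes) -
    tt$sdlog * stats::qnorm(1 - tt$share_ge_threshold)
  cov$travel_time_minutes <- round(stats::rlnorm(n, mu, tt$sdlog), 1)
  cov$travel_class <- classify_travel_time(cov$travel_time_minutes, spec)
  cov
}

# Hospital frame: correlated performance indicators via a Gaussian copula
# over two Beta marginals, lognormal volume weights, Gaussian random
# intercepts on the logit scale.
sample_hospital_frame <- function(cfg) {
  m <- cfg$n_hospitals
  hd <- cfg$hospital_metric_distributions
  z1 <- stats::rnorm(m)
  z2 <- hd$copula_rho * z1 + sqrt(1 - hd$copula_rho^2) * stats::rnorm(m)
  data.frame(
    hospital_id = sprintf("H%03d", seq_len(m)),
    latent_p_pci = stats::qbeta(stats::pnorm(z1), hd$p_pci$shape1, hd$p_pci$shape2),
    latent_p_timely = stats::qbeta(stats::pnorm(z2), hd$p_timely$shape1,
                                   hd$p_timely$shape2),
    weight = stats::rlnorm(m, 0, hd$volume_sdlog),
    re = stats::rnorm(m, 0, cfg$hospital_re_sd),
    stringsAsFactors = FALSE
  )
}

# One forward pass of the three-phase process. With `intercepts = NULL` the
# per-phase intercepts are solved sequentially on the realized at-risk sets
# so the population-average survival per phase hits cfg$phase_marginals.
simulate_core <- function(cfg, n, seed, intercepts = NULL,
                          spec = exposure_spec()) {
  set.seed(derive_seed(seed, "core"))
  eff <- cfg$phase_effects
  pm <- cfg$phase_marginals
  solve_a <- function(eta, k, phase) {
    if (!is.null(intercepts)) return(unname(intercepts[k]))
    solve_marginal_intercept(eta, pm[k], label = phase)
  }

  cov <- sample_covariates(cfg, n, spec)
  eta1 <- phase_linpred(cov, eff$emergency)
  a1 <- solve_a(eta1, 1L, "emergency")
  y1 <- stats::runif(n) < stats::plogis(a1 + eta1)

  hosp <- sample_hospital_frame(cfg)
  stemi <- y1 & (stats::runif(n) < cfg$stemi_share)
  hosp_idx <- rep(NA_integer_, n)
  hosp_idx[y1] <- sample.int(nrow(hosp), sum(y1), replace = TRUE,
                             prob = hosp$weight)

  # admission-level procedure indicators for STEMI admissions
  ns <- sum(stemi)
  hs <- hosp_idx[stemi]
  pci <- stats::runif(ns) < hosp$latent_p_pci[hs]
  reperf <- pci & (stats::runif(ns) < 0.92)
  timely <- reperf & (stats::runif(ns) < hosp$latent_p_timely[hs])
  d2b <- rep(NA_real_, ns)
  d2b[timely] <- round(stats::runif(sum(timely), 25, 90))
  d2b[reperf & !timely] <- round(stats::runif(sum(reperf & !timely), 91, 360))

  stemi_adm <- data.frame(hospital_id = hosp$hospital_id[hs], pci = pci,
                          reperf_12h = reperf, door_to_balloon_min = d2b,
                          stringsAsFactors = FALSE)
  profiles <- suppressWarnings(
    hospital_performance(build_hospital_profiles(stemi_adm), spec))
  hosp$performance_class <- factor(
    profiles$performance_class[match(hosp$hospital_id, profiles$hospital_id)],
    levels = hosp_levels())
  hosp$performance_class[is.na(hosp$performance_class)] <- "medium"

  cov$hosp_class <- factor(NA_character_, levels = hosp_levels())
  cov$hosp_class[stemi] <- hosp$performance_class[hs]
  y2 <- rep(NA, n)
  a2 <- NA_real_
  if (ns > 0) {
    eta2 <- phase_linpred(cov[stemi, , drop = FALSE], eff$acute) + hosp$re[hs]
    a2 <- solve_a(eta2, 2L, "acute")
    y2[stemi] <- stats::runif(ns) < stats::plogis(a2 + eta2)
  }

  surv30 <- stemi & (y2 %in% TRUE)
  excl_d30 <- surv30 & (stats::runif(n) < cfg$excl_death30_frac)
  excl_long <- surv30 & (stats::runif(n) < cfg$excl_longstay_frac)

  # post-discharge EB drug regimen for every 30-day survivor
  cov$drug_class <- factor(NA_character_, levels = drug_levels())
  n30 <- sum(surv30)
  if (n30 > 0) {
    cls <- sample_levels(n30, cfg$drug_class_shares)
    low_counts <- as.integer(as.character(sample_levels(n30, cfg$low_drug_split)))
    n_distinct <- integer(n30)
    low <- cls == "<=2"
    n_distinct[low] <- low_counts[low]
    n_distinct[!low] <- as.integer(as.character(cls[!low]))
    cov$drug_class[surv30] <- cls
  } else {
    n_distinct <- integer(0)
  }

  postacute <- surv30 & !excl_d30 & !excl_long
  y3 <- rep(NA, n)
  a3 <- NA_real_
  if (any(postacute)) {
    eta3 <- phase_linpred(cov[postacute, , drop = FALSE], eff$postacute) +
      hosp$re[hosp_idx[postacute]]
    a3 <- solve_a(eta3, 3L, "postacute")
    y3[postacute] <- stats::runif(sum(postacute)) < stats::plogis(a3 + eta3)
  }

  list(cov = cov, y1 = y1, y2 = y2, y3 = y3, stemi = stemi,
       hosp_idx = hosp_idx, hospitals = hosp, surv30 = surv30,
       excl_d30 = excl_d30, excl_long = excl_long,
       n_distinct_drugs = n_distinct,
       stemi_pci = pci, stemi_reperf = reperf, stemi_d2b = d2b,
       intercepts = c(emergency = a1, acute = a2, postacute = a3))
}

#' Calibrate per-phase model intercepts to the target marginals
#'
#' Solves, phase by phase, for the logistic intercept at which the
#' population-average simulated survival probability over `n_cal` sampled
#' patient profiles (covariates, exposures, and hospital random intercepts,
#' with each phase's at-risk set selected by the previous phases) equals the
#' configured phase marginal. The root search is monotone and errors,
#' naming the phase, if no root can be bracketed.
#'
#' @param cfg An [mpc_calibration][new_calibration] object.
#' @param n_cal Number of simulated profiles (at least 1000; default 2e5).
#' @param seed Integer seed; the result is deterministic given `(cfg, seed)`.
#' @param tol Calibration tolerance on the probability scale.
#' @return Named numeric vector of intercepts (logit scale) for the
#'   emergency, acute and post-acute phases.
#' @export
calibrate_intercepts <- function(cfg, n_cal = 200000L, seed = 20110101L,
                                 tol = 1e-3) {
  validate_calibration(cfg)
  stopifnot(n_cal >= 1000L)
  core <- simulate_core(cfg, as.integer(n_cal), seed)
  core$intercepts
}

#' Generate a linked synthetic registry
#'
#' Simulates the full three-phase survival process under the calibration
#' configuration and emits it as five linked tables mimicking a regional
#' health information system:
#'
#' * `patients`: demographics, chronic conditions, prior-drug flags and
#'   home-to-hospital travel time (minutes);
#' * `admissions`: index AMI admissions (ICD-9-CM main diagnosis 410),
#'   pre-index history admissions carrying the comorbidity diagnoses, and
#'   prior AMI admissions for a configurable fraction of extra *prevalent*
#'   patients (excluded downstream by the 3-year washout);
#' * `prescriptions`: ATC-coded dispensings in the 6 months before the
#'   index event (co-medication groups) and in the 30 days after discharge
#'   (EB secondary-prevention classes);
#' * `deaths`: out-of-hospital ischemic deaths (cause ICD-9 410--414, no
#'   index admission), 30-day deaths, deaths within 30 days of discharge
#'   (post-acute exclusions) and 31--365-day deaths;
#' * `hospitals`: per-hospital PCI counts/timeliness profile with the
#'   quartile-based performance class.
#'
#' Identical `(cfg, seed)` yield identical bundles. By default the
#' per-phase intercepts are solved on the cohort's own realized profiles
#' (hospital frame included), so the population-average survival of each
#' phase matches the configured marginal up to pure Bernoulli draw noise;
#' fixed intercepts (e.g. from [calibrate_intercepts()]) can be supplied
#' instead to hold the data-generating model constant across bundles.
#'
#' @param cfg An [mpc_calibration][new_calibration] object.
#' @param seed Integer seed.
#' @param intercepts Optional fixed per-phase intercepts (logit scale).
#' @return A `registry_bundle`: list of the five tables plus the
#'   configuration, seed and intercepts used.
#' @export
generate_registry <- function(cfg, seed = 20110101L, intercepts = NULL) {
  validate_calibration(cfg)
  spec <- exposure_spec()
  core <- simulate_core(cfg, cfg$n_patients, derive_seed(seed, "registry"),
                        intercepts = intercepts, spec = spec)
  intercepts <- core$intercepts
  set.seed(derive_seed(seed, "tables"))

  n <- cfg$n_patients
  cov <- core$cov
  period <- as_date(c(cfg$study_period$start, cfg$study_period$end))
  index_date <- period[1] + sample.int(as.integer(period[2] - period[1]) + 1L,
                                       n, replace = TRUE) - 1L
  pid <- sprintf("P%06d", seq_len(n))

  patients <- data.frame(patient_id = pid,
                         cov[, setdiff(names(cov),
                                       c("travel_class", "hosp_class",
                                         "drug_class"))],
                         stringsAsFactors = FALSE)

  ## --- index admissions (patients reaching hospital alive) ---------------
  alive <- core$y1
  stemi <- core$stemi
  hosp_of <- core$hospitals$hospital_id[core$hosp_idx]
  main_dx <- paste0("410", sample(c("01", "11", "21", "41", "71", "91"),
                                  n, replace = TRUE))
  # length of stay: 30-day deaths die in hospital; long-stay exclusions >28 d
  death_day30 <- rep(NA_integer_, n)
  acute_death <- stemi & (core$y2 %in% FALSE)
  death_day30[acute_death] <- pmin(
    1L + stats::rpois(sum(acute_death), 6), 30L)
  los <- pmin(1L + stats::rpois(n, cfg$los_mean_days - 1), 28L)
  los[core$excl_long] <- 29L + stats::rpois(sum(core$excl_long), 4)
  los[acute_death] <- death_day30[acute_death]
  discharge_date <- index_date + los

  adm_index <- data.frame(
    patient_id = pid[alive],
    hospital_id = hosp_of[alive],
    admission_date = index_date[alive],
    discharge_date = discharge_date[alive],
    main_dx = main_dx[alive],
    secondary_dx = ifelse(cov$diabetes[alive], "25000", ""),
    stemi = stemi[alive],
    pci = FALSE, reperf_12h = FALSE, door_to_balloon_min = NA_real_,
    stringsAsFactors = FALSE
  )
  # transfer the procedure indicators drawn in simulate_core (aligned with
  # which(stemi), the row order of the STEMI subset of adm_index)
  adm_index$pci[adm_index$stemi] <- core$stemi_pci
  adm_index$reperf_12h[adm_index$stemi] <- core$stemi_reperf
  adm_index$door_to_balloon_min[adm_index$stemi] <- core$stemi_d2b

  ## --- history admissions (comorbidity lookback records) -----------------
  hist_list <- list()
  for (cm in names(icd9_comorbidity_codes)) {
    has <- which(cov[[cm]])
    if (!length(has)) next
    hist_list[[cm]] <- data.frame(
      patient_id = pid[has],
      hospital_id = sample(core$hospitals$hospital_id, length(has),
                           replace = TRUE),
      admission_date = index_date[has] -
        sample(30:729, length(has), replace = TRUE),
      main_dx = sample(icd9_comorbidity_codes[[cm]], length(has),
                       replace = TRUE),
      secondary_dx = "",
      stemi = FALSE, pci = FALSE, reperf_12h = FALSE,
      door_to_balloon_min = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  hist_adm <- do.call(rbind, hist_list)
  if (!is.null(hist_adm)) {
    hist_adm$discharge_date <- hist_adm$admission_date +
      sample(1:10, nrow(hist_adm), replace = TRUE)
    hist_adm <- hist_adm[, names(adm_index)]
  }

  ## --- prevalent extra patients (exercise the 3-year washout) ------------
  m <- round(cfg$prevalent_frac * n)
  prev_tabs <- NULL
  if (m > 0) {
    pcov <- sample_covariates(cfg, m, spec)
    xid <- sprintf("X%05d", seq_len(m))
    u <- sample(30:1000, m, replace = TRUE)
    prior_date <- period[1] - u
    idx_date <- prior_date + u +
      floor(stats::runif(m) * (1094 - u))  # within 3 years of the prior AMI
    prev_patients <- data.frame(patient_id = xid,
                                pcov[, setdiff(names(pcov),
                                               c("travel_class", "hosp_class",
                                                 "drug_class"))],
                                stringsAsFactors = FALSE)
    prev_adm <- data.frame(
      patient_id = rep(xid, 2L),
      hospital_id = sample(core$hospitals$hospital_id, 2L * m, replace = TRUE),
      admission_date = c(prior_date, idx_date),
      discharge_date = c(prior_date, idx_date) +
        sample(2:12, 2L * m, replace = TRUE),
      main_dx = paste0("410", sample(c("11", "71", "91"), 2L * m,
                                     replace = TRUE)),
      secondary_dx = "",
      stemi = FALSE, pci = FALSE, reperf_12h = FALSE,
      door_to_balloon_min = NA_real_,
      stringsAsFactors = FALSE
    )
    prev_tabs <- list(patients = prev_patients, admissions = prev_adm)
  }

  ## --- deaths -------------------------------------------------------------
  death_list <- list()
  ooh <- !alive
  if (any(ooh)) {
    death_list$ooh <- data.frame(
      patient_id = pid[ooh],
      death_date = index_date[ooh],
      cause_icd9 = sample(c("410", "411", "412", "414"), sum(ooh),
                          replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
      stringsAsFactors = FALSE
    )
  }
  if (any(acute_death)) {
    death_list$acute <- data.frame(
      patient_id = pid[acute_death],
      death_date = index_date[acute_death] + death_day30[acute_death],
      cause_icd9 = "410", stringsAsFactors = FALSE
    )
  }
  if (any(core$excl_d30)) {
    w <- which(core$excl_d30)
    kmin <- pmax(1L, 31L - los[w])
    k <- kmin + floor(stats::runif(length(w)) * (31L - kmin))
    death_list$excl <- data.frame(
      patient_id = pid[w],
      death_date = discharge_date[w] + k,
      cause_icd9 = sample(c("410", "428"), length(w), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  late_death <- core$y3 %in% FALSE
  if (any(late_death)) {
    w <- which(late_death)
    death_list$late <- data.frame(
      patient_id = pid[w],
      death_date = discharge_date[w] + sample(31:365, length(w), replace = TRUE),
      cause_icd9 = sample(c("410", "414", "428", "162"), length(w),
                          replace = TRUE, prob = c(0.4, 0.2, 0.3, 0.1)),
      stringsAsFactors = FALSE
    )
  }
  deaths <- do.call(rbind, death_list)
  rownames(deaths) <- NULL

  ## --- prescriptions ------------------------------------------------------
  comed_atc <- c(pre_cardiac = "C01AA05", pre_antiplatelet = "B01AC06",
                 pre_anticoagulant = "B01AA03", pre_antihypertensive = "C02AC01",
                 pre_diuretic = "C03CA01", pre_betablocker = "C07AB07",
                 pre_ccb = "C08CA01", pre_acei = "C09AA05", pre_arb = "C09CA01",
                 pre_statin = "C10AA05")
  rx_list <- list()
  for (dr in names(comed_atc)) {
    has <- which(cov[[dr]])
    if (!length(has)) next
    rx_list[[dr]] <- data.frame(
      patient_id = pid[has],
      atc = comed_atc[[dr]],
      dispense_date = index_date[has] - sample(1:179, length(has), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  # post-discharge EB dispensings realizing the assigned regimen class
  surv30_idx <- which(core$surv30)
  if (length(surv30_idx)) {
    eb_codes <- list(antiplatelet = c("B01AC04", "B01AC05", "B01AC06"),
                     betablocker = "C07AB07", acei_arb = c("C09AA05", "C09CA01"),
                     statin = "C10AA05")
    k <- core$n_distinct_drugs  # aligned with surv30_idx order
    pick <- lapply(k, function(kk) sample(names(eb_codes), kk))
    reps <- lengths(pick)
    if (sum(reps)) {
      who <- rep(surv30_idx, reps)
      classes <- unlist(pick)
      atc <- vapply(classes, function(cl) {
        codes <- eb_codes[[cl]]
        codes[sample.int(length(codes), 1L)]
      }, character(1))
      rx_list$eb <- data.frame(
        patient_id = pid[who],
        atc = unname(atc),
        dispense_date = discharge_date[who] +
          sample(1:30, length(who), replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
  }
  prescriptions <- do.call(rbind, rx_list)
  rownames(prescriptions) <- NULL

  ## --- assemble ------------------------------------------------------------
  admissions <- rbind(adm_index, hist_adm)
  if (!is.null(prev_tabs)) {
    patients <- rbind(patients, prev_tabs$patients)
    admissions <- rbind(admissions, prev_tabs$admissions)
  }
  admissions <- admissions[order(admissions$patient_id,
                                 admissions$admission_date), ]
  rownames(admissions) <- NULL

  hospitals <- suppressWarnings(hospital_performance(
    build_hospital_profiles(adm_index[adm_index$stemi, , drop = FALSE]), spec))
  hospitals$random_intercept <- core$hospitals$re[
    match(hospitals$hospital_id, core$hospitals$hospital_id)]

  structure(list(patients = patients, admissions = admissions,
                 prescriptions = prescriptions, deaths = deaths,
                 hospitals = hospitals, config = cfg, seed = seed,
                 intercepts = intercepts),
            class = "registry_bundle")
}

#' @export
#' @method print registry_bundle
print.registry_bundle <- function(x, ...) {
  cat("<registry_bundle> seed", x$seed, "\n")
  for (t in c("patients", "admissions", "prescriptions", "deaths", "hospitals")) {
    cat(sprintf("  %-13s %8d rows\n", t, nrow(x[[t]])))
  }
  invisible(x)
}
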