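# Shared fixtures, built lazily and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

# small but fully structured registry for structural / builder tests
small_cfg <- function(...) {
  new_calibration(n_patients = 3000L, n_hospitals = 12L, ...)
}

small_bundle <- function() {
  if (is.null(.fixtures$small_bundle)) {
    .fixtures$small_bundle <- generate_registry(small_cfg(), seed = 20110101L)
  }
  .fixtures$small_bundle
}

small_cohort <- function() {
  if (is.null(.fixtures$small_cohort)) {
    b <- small_bundle()
    .fixtures$small_cohort <- classify_exposures(build_cohort(b), b)
  }
  .fixtures$small_cohort
}

# phase effects with every odds ratio at 1 (null-exposure calibration)
null_effects <- function() {
  eff <- mpcsurv:::default_phase_effects()
  for (ph in names(eff)) {
    for (nm in names(eff[[ph]])) {
      eff[[ph]][[nm]][] <- 1
    }
  }
  eff
}

# exact-coefficient logistic phase model: fits on balanced constructed data
# so the fitted coefficients equal stated logits exactly
exact_travel_model <- function(p_low, p_high, n_per = 600L, phase = "emergency") {
  lv <- c("<10", ">=10")
  mk <- function(level, p) {
    k <- round(p * n_per)
    data.frame(travel_class = factor(level, levels = lv),
               y = rep(c(TRUE, FALSE), c(k, n_per - k)))
  }
  d <- rbind(mk("<10", p_low), mk(">=10", p_high))
  fit_logistic(d, "y", "travel_class", phase = phase)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
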