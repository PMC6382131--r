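# The chained survival computation: g-computation scenario standardization
# per phase, product of the three conditional survival probabilities,
# best-vs-worst probability ratios with bootstrap percentile intervals,
# expected lives saved, and subgroup contrasts.

# Fixed-effect linear predictor for new data under either model class.
fixed_linpred <- function(model, newdata) {
  if (inherits(model$fit, "merMod")) {
    stats::predict(model$fit, newdata = newdata, re.form = NA, type = "link")
  } else {
    stats::predict(model$fit, newdata = newdata, type = "link")
  }
}

# Population-averaged success probabilities: the hospital random intercept
# is integrated out over its fitted N(0, re_sd^2) distribution by
# Gauss-Hermite quadrature (conditional mode set to zero is available as
# re_method = "zero").
averaged_prob <- function(model, eta, re_method = "integrate",
                          quad_points = 21L) {
  if (is.na(model$re_sd) || model$re_sd == 0 || re_method == "zero") {
    return(stats::plogis(eta))
  }
  gh <- lme4::GHrule(quad_points)
  p <- numeric(length(eta))
  for (k in seq_len(nrow(gh))) {
    p <- p + gh[k, "w"] * stats::plogis(eta + model$re_sd * gh[k, "z"])
  }
  p
}

# Overwrite the exposure columns present in the model with scenario levels.
apply_scenario <- function(model, population, scenario) {
  for (nm in intersect(names(scenario), model$terms)) {
    col <- population[[nm]]
    if (!is.factor(col)) stop("exposure column not a factor: ", nm)
    if (!scenario[[nm]] %in% levels(col)) {
      stop("scenario level '", scenario[[nm]], "' absent from coding of ", nm)
    }
    population[[nm]] <- factor(scenario[[nm]], levels = levels(col))
  }
  population
}

#' Standardized phase survival probability under a care scenario
#'
#' G-computation (marginal standardization): every patient in the reference
#' population keeps their observed covariates, the phase exposure(s) are
#' set to the scenario values, the model probability is computed per
#' patient, and the population mean is returned. This is the survival
#' probability of the *mean-severity* patient under the scenario: a patient
#' with the covariate distribution of the reference population. For
#' multilevel models the hospital random intercept is integrated out, so
#' the result is a population-averaged probability.
#'
#' @param model An `mpc_phase_model` (must have converged).
#' @param population Analysis rows serving as the standardization
#'   population.
#' @param scenario Named list/vector of exposure levels, e.g.
#'   `list(travel_class = "<10", hosp_class = "high", drug_class = "4")`;
#'   only the exposures present in the model are used.
#' @param re_method `"integrate"` (default, population-averaged) or
#'   `"zero"` (conditional on the median hospital).
#' @param quad_points Gauss-Hermite order for the integration.
#' @return A single probability.
#' @export
standardized_probability <- function(model, population, scenario,
                                     re_method = "integrate",
                                     quad_points = 21L) {
  if (!isTRUE(model$converged)) {
    warning("standardizing over a model flagged non-converged")
  }
  if (!nrow(population)) stop("empty standardization population")
  nd <- apply_scenario(model, population, scenario)
  eta <- fixed_linpred(model, nd)
  mean(averaged_prob(model, eta, re_method, quad_points))
}

#' Chain three conditional survival probabilities
#'
#' The overall 1-year survival probability is the product of the
#' probability of reaching the hospital alive, the conditional 30-day
#' survival probability, and the conditional 31--365-day survival
#' probability.
#'
#' @param p1,p2,p3 Probabilities in \[0, 1\].
#' @return `p1 * p2 * p3`.
#' @export
chain <- function(p1, p2, p3) {
  p <- c(p1, p2, p3)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("phase probabilities must lie in [0, 1]")
  }
  p1 * p2 * p3
}

#' Per-phase standardization populations of an analysis cohort
#'
#' The survival probability of each phase is standardized over that
#' phase's own analysis cohort — all index events for the emergency phase,
#' STEMI admissions for the acute phase, the post-acute analysis set for
#' the post-acute phase — mirroring the per-phase model cohorts.
#'
#' @param rows Analysis table from [build_cohort()] /
#'   [classify_exposures()].
#' @return Named list of three data frames
#'   (`emergency`, `acute`, `postacute`).
#' @export
phase_populations <- function(rows) {
  list(emergency = rows,
       acute = rows[rows$stemi %in% TRUE, , drop = FALSE],
       postacute = rows[rows$postacute %in% TRUE, , drop = FALSE])
}

as_phase_populations <- function(population) {
  if (is.data.frame(population)) {
    list(emergency = population, acute = population, postacute = population)
  } else {
    stopifnot(all(c("emergency", "acute", "postacute") %in% names(population)))
    population
  }
}

#' Standardized scenario survival and scenario probability ratio
#'
#' `scenario_survival()` returns the three standardized phase probabilities
#' and their product for one scenario; `scenario_pr()` forms the ratio of
#' the chained survival under scenario A to that under scenario B, both
#' standardized over the same reference population(s).
#'
#' @param models Named list of the three `mpc_phase_model`s
#'   (`emergency`, `acute`, `postacute`).
#' @param population Reference population: either a per-phase list as
#'   produced by [phase_populations()] (the default convention — each
#'   phase standardized over its own analysis cohort), or a single data
#'   frame used for all three phases.
#' @param scenario,scenario_a,scenario_b Scenario exposure-level lists from
#'   the 18-scenario lattice ([enumerate_scenarios()]).
#' @param ... Passed to [standardized_probability()].
#' @return `scenario_survival()`: list with `p1`, `p2`, `p3`, `p_overall`.
#'   `scenario_pr()`: list with `pr`, the two scenario summaries, and the
#'   population size(s).
#' @export
scenario_survival <- function(models, population, scenario, ...) {
  pop <- as_phase_populations(population)
  p1 <- standardized_probability(models$emergency, pop$emergency, scenario, ...)
  p2 <- standardized_probability(models$acute, pop$acute, scenario, ...)
  p3 <- standardized_probability(models$postacute, pop$postacute, scenario, ...)
  list(p1 = p1, p2 = p2, p3 = p3, p_overall = chain(p1, p2, p3))
}

#' @rdname scenario_survival
#' @export
scenario_pr <- function(models, population, scenario_a, scenario_b, ...) {
  pop <- as_phase_populations(population)
  a <- scenario_survival(models, pop, scenario_a, ...)
  b <- scenario_survival(models, pop, scenario_b, ...)
  if (b$p_overall == 0) stop("zero overall survival under comparison scenario")
  list(pr = a$p_overall / b$p_overall, scenario_a = a, scenario_b = b,
       n = vapply(pop, nrow, integer(1)))
}

#' Standardized survival for every scenario in the lattice
#'
#' @inheritParams scenario_survival
#' @param spec An [exposure_spec()].
#' @return The 18-row scenario data frame with `p1`, `p2`, `p3` and
#'   `p_overall` columns appended.
#' @export
scenario_table <- function(models, population, spec = exposure_spec(), ...) {
  sc <- enumerate_scenarios(spec)
  res <- t(vapply(seq_len(nrow(sc)), function(i) {
    s <- scenario_survival(models, population,
                           list(travel_class = as.character(sc$travel_class[i]),
                                hosp_class = as.character(sc$hosp_class[i]),
                                drug_class = as.character(sc$drug_class[i])),
                           ...)
    c(p1 = s$p1, p2 = s$p2, p3 = s$p3, p_overall = s$p_overall)
  }, numeric(4)))
  cbind(sc, as.data.frame(res))
}

#' Bootstrap percentile confidence interval for a probability ratio
#'
#' Draws with-replacement resamples of the analysis rows (each patient
#' carries their hospital assignment), re-runs the supplied pipeline
#' closure (which re-fits the models and recomputes the PR) on every
#' resample, and returns the 2.5/97.5 percentile bounds of the resampled
#' point estimates. Failed resample fits are skipped; more than 10%
#' failures is an error.
#'
#' @param pipeline Function `data -> numeric PR`.
#' @param data Analysis rows to resample.
#' @param n_bootstrap Number of resamples.
#' @param seed Integer seed.
#' @param level Interval coverage (default 0.95).
#' @return List: `pr` (full-data point estimate), `bci_low`, `bci_high`,
#'   `n_bootstrap`, `n_failed`, and the vector of resampled estimates.
#' @export
bootstrap_pr_ci <- function(pipeline, data, n_bootstrap = 1000L,
                            seed = 20110101L, level = 0.95) {
  point <- pipeline(data)
  set.seed(seed)
  prs <- rep(NA_real_, n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    i <- sample.int(nrow(data), nrow(data), replace = TRUE)
    prs[b] <- tryCatch(pipeline(data[i, , drop = FALSE]),
                       error = function(e) NA_real_)
  }
  failed <- sum(is.na(prs))
  if (failed > 0.10 * n_bootstrap) {
    stop("bootstrap PR: ", failed, " of ", n_bootstrap, " resample fits failed")
  }
  q <- stats::quantile(prs, c((1 - level) / 2, 1 - (1 - level) / 2),
                       na.rm = TRUE, names = FALSE)
  list(pr = point, bci_low = q[1], bci_high = q[2],
       n_bootstrap = n_bootstrap, n_failed = failed, replicates = prs)
}

#' Expected lives saved by upgrading worst-level exposures to best level
#'
#' For each phase, patients observed at the phase's worst exposure level
#' (travel time at/above threshold; low-performance hospital; at most 2 EB
#' drugs) have that exposure replaced by the phase's best level, all other
#' covariates held at their observed values. The expected additional
#' survivors are accumulated through the chain by summing, per phase, the
#' change in model probability over the phase's observed at-risk set
#' (each later at-risk set already conditions on survival of the earlier
#' phases):
#' `sum_k sum_{i in risk_k, x_k(i) = worst_k} [p_k(best; i) - p_k(obs; i)]`.
#'
#' @param models The three fitted phase models.
#' @param rows Analysis table with observed exposures.
#' @param spec An [exposure_spec()].
#' @param ... Passed to the underlying probability computations.
#' @return Expected number of additional survivors (a real number).
#' @export
lives_saved <- function(models, rows, spec = exposure_spec(), ...) {
  best <- best_scenario(spec)
  worst <- worst_scenario(spec)
  risk <- list(
    emergency = list(rows, "travel_class"),
    acute = list(rows[rows$stemi %in% TRUE, , drop = FALSE], "hosp_class"),
    postacute = list(rows[rows$postacute %in% TRUE, , drop = FALSE],
                     "drug_class")
  )
  total <- 0
  for (phase in names(risk)) {
    d <- risk[[phase]][[1]]
    expo <- risk[[phase]][[2]]
    d <- d[!is.na(d[[expo]]) & d[[expo]] == worst[[expo]], , drop = FALSE]
    if (!nrow(d)) next
    m <- models[[phase]]
    p_obs <- averaged_prob(m, fixed_linpred(m, d), ...)
    d_best <- d
    d_best[[expo]] <- factor(best[[expo]], levels = levels(d[[expo]]))
    p_best <- averaged_prob(m, fixed_linpred(m, d_best), ...)
    total <- total + sum(p_best - p_obs)
  }
  total
}

#' Best-versus-worst probability ratios within subgroups
#'
#' Recomputes the best-vs-worst scenario PR with the standardization
#' population restricted to each level of a stratifier (gender, age class,
#' diabetes, COPD). By default the pooled phase models are used with
#' stratum-restricted standardization; with `refit = TRUE` the three
#' models are re-fitted within each stratum (the stratifier itself dropped
#' from the terms).
#'
#' @param models The three fitted phase models.
#' @param rows Full analysis table.
#' @param stratifier Column name: one of `"sex"`, `"age_class"`,
#'   `"diabetes"`, `"copd"` (any factor/logical column works).
#' @param spec An [exposure_spec()].
#' @param refit Re-fit models per stratum?
#' @param min_rows Strata with fewer rows are skipped with a warning.
#' @param nAGQ Integration order for refitted multilevel models.
#' @param ... Passed to [standardized_probability()].
#' @return Data frame: stratifier, level, n, standardized best and worst
#'   overall survival, and their ratio.
#' @export
subgroup_prs <- function(models, rows, stratifier, spec = exposure_spec(),
                         refit = FALSE, min_rows = 50L, nAGQ = 1L, ...) {
  x <- rows[[stratifier]]
  if (is.null(x)) stop("unknown stratifier column: ", stratifier)
  levs <- if (is.factor(x)) levels(x) else sort(unique(x))
  best <- best_scenario(spec)
  worst <- worst_scenario(spec)
  pops <- phase_populations(rows)
  out <- list()
  for (lv in levs) {
    sub <- rows[x == lv, , drop = FALSE]
    sub_pops <- lapply(pops, function(p) p[p[[stratifier]] == lv, , drop = FALSE])
    if (nrow(sub) < min_rows) {
      warning("stratum ", stratifier, "=", lv, " has fewer than ", min_rows,
              " rows; skipped")
      next
    }
    mods <- models
    if (refit) {
      sub2 <- sub
      keep <- function(tms) setdiff(tms, stratifier)
      mods <- list(
        emergency = fit_logistic(sub2, models$emergency$outcome,
                                 keep(models$emergency$terms), "emergency"),
        acute = fit_multilevel_logistic(
          sub2[sub2$stemi %in% TRUE, , drop = FALSE], models$acute$outcome,
          keep(models$acute$terms), nAGQ = nAGQ, phase = "acute"),
        postacute = fit_multilevel_logistic(
          sub2[sub2$postacute %in% TRUE, , drop = FALSE],
          models$postacute$outcome, keep(models$postacute$terms),
          nAGQ = nAGQ, phase = "postacute")
      )
    }
    pr <- scenario_pr(mods, sub_pops, best, worst, ...)
    out[[length(out) + 1L]] <- data.frame(
      stratifier = stratifier, level = as.character(lv), n = nrow(sub),
      p_best = pr$scenario_a$p_overall, p_worst = pr$scenario_b$p_overall,
      pr = pr$pr, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
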