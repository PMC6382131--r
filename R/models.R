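# Phase-specific outcome models: ordinary and random-intercept logistic
# regression, Wald summaries, and bootstrap stepwise covariate selection.

#' Specification for bootstrap stepwise covariate selection
#'
#' @param n_bootstrap Number of with-replacement resamples (default 1000).
#' @param alpha Entry and removal threshold on likelihood-ratio p-values.
#' @param inclusion_threshold Minimum fraction of resamples in which a
#'   candidate must be selected to enter the final model (default 0.5).
#' @param forced_terms Terms always kept in the model regardless of
#'   selection (a priori risk factors; default age class and sex).
#' @param seed Integer seed making the procedure deterministic.
#' @return An object of class `mpc_selection_spec`.
#' @export
selection_spec <- function(n_bootstrap = 1000L, alpha = 0.05,
                           inclusion_threshold = 0.5,
                           forced_terms = c("sex", "age_class"),
                           seed = 20110101L) {
  stopifnot(alpha > 0, alpha < 1, inclusion_threshold > 0,
            inclusion_threshold <= 1, n_bootstrap >= 1)
  structure(list(n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 inclusion_threshold = inclusion_threshold,
                 forced_terms = forced_terms, seed = as.integer(seed)),
            class = "mpc_selection_spec")
}

# Covariate terms of the full adjustment set (demographics, chronic
# conditions, comorbidity lookback flags, prior-drug flags).
adjustment_terms <- function() {
  c("sex", "age_class", "diabetes", "copd",
    names(icd9_comorbidity_codes), names(atc_comed_codes))
}

phase_exposure_terms <- function(phase) {
  switch(phase,
         emergency = "travel_class",
         acute = c("travel_class", "hosp_class"),
         postacute = c("travel_class", "hosp_class", "drug_class"),
         stop("unknown phase: ", phase))
}

phase_outcome_var <- function(phase) {
  switch(phase,
         emergency = "survived_emergency",
         acute = "survived_30d",
         postacute = "survived_31_365",
         stop("unknown phase: ", phase))
}

new_phase_model <- function(fit, phase, outcome, terms, cluster = NULL) {
  is_ml <- inherits(fit, "merMod")
  if (is_ml) {
    co <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(suppressWarnings(stats::vcov(fit)))))
    re_sd <- sqrt(unname(lme4::VarCorr(fit)[[cluster]][1, 1]))
    # a singular fit (variance on the boundary) is a valid estimate; only
    # optimizer failure / non-convergence messages flag the fit
    msgs <- fit@optinfo$conv$lme4$messages %||% character(0)
    conv <- isTRUE(fit@optinfo$conv$opt == 0L) &&
      !any(grepl("failed to converge", msgs, fixed = TRUE))
    ll <- as.numeric(stats::logLik(fit))
  } else {
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    re_sd <- NA_real_
    conv <- isTRUE(fit$converged)
    ll <- as.numeric(stats::logLik(fit))
  }
  structure(list(phase = phase, outcome = outcome, terms = terms,
                 coefficients = co, se = se, re_sd = re_sd,
                 cluster = cluster, loglik = ll, converged = conv,
                 n = stats::nobs(fit), fit = fit),
            class = "mpc_phase_model")
}

#' @export
#' @method print mpc_phase_model
print.mpc_phase_model <- function(x, ...) {
  cat(sprintf("<mpc_phase_model> phase=%s outcome=%s n=%d%s\n", x$phase,
              x$outcome, x$n,
              if (!is.na(x$re_sd)) sprintf(" re_sd=%.3f", x$re_sd) else ""))
  print(round(cbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

phase_formula <- function(outcome, terms, cluster = NULL) {
  rhs <- paste(terms, collapse = " + ")
  if (!is.null(cluster)) rhs <- paste0(rhs, " + (1 | ", cluster, ")")
  stats::as.formula(paste(outcome, "~", rhs))
}

#' Fit a phase outcome model by maximum-likelihood logistic regression
#'
#' @param data Analysis rows restricted to the phase's at-risk set; the
#'   outcome column must be logical (or 0/1) with both values present.
#' @param outcome Name of the binary outcome column.
#' @param terms Character vector of model terms; categorical covariates
#'   enter as whole factors.
#' @param phase Optional phase label carried on the result.
#' @return An `mpc_phase_model` with coefficients on the log-odds scale,
#'   Wald standard errors and a convergence flag. Perfect separation and
#'   rank deficiency raise errors naming the offending terms.
#' @export
fit_logistic <- function(data, outcome, terms, phase = NA_character_) {
  f <- phase_formula(outcome, terms)
  fit <- suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient fit; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  big <- abs(stats::coef(fit)) > 15
  if (any(big)) {
    stop("apparent separation on term(s): ",
         paste(names(stats::coef(fit))[big], collapse = ", "))
  }
  new_phase_model(fit, phase, outcome, terms)
}

#' Fit a random-intercept (multilevel) phase model
#'
#' Random-intercept logistic regression with one intercept per cluster
#' (hospital of admission), estimated by adaptive Gauss-Hermite /
#' Laplace-approximated maximum likelihood via [lme4::glmer()].
#'
#' @inheritParams fit_logistic
#' @param cluster Name of the cluster identifier column.
#' @param nAGQ Integration order for the likelihood approximation
#'   (1 = Laplace; higher = adaptive Gauss-Hermite).
#' @return An `mpc_phase_model` carrying fixed effects and the estimated
#'   random-intercept standard deviation. With a single cluster the model
#'   degrades to [fit_logistic()] with a warning.
#' @export
fit_multilevel_logistic <- function(data, outcome, terms,
                                    cluster = "hospital_id", nAGQ = 1L,
                                    phase = NA_character_) {
  k <- length(unique(data[[cluster]]))
  if (k < 2L) {
    warning("fewer than 2 clusters; falling back to ordinary logistic fit")
    return(fit_logistic(data, outcome, terms, phase))
  }
  f <- phase_formula(outcome, terms, cluster)
  fit <- suppressWarnings(suppressMessages(
    lme4::glmer(f, data = data, family = stats::binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(optimizer = "bobyqa",
                                             optCtrl = list(maxfun = 1e5)))))
  new_phase_model(fit, phase, outcome, terms, cluster)
}

#' Adjusted odds ratio for a model term
#'
#' @param model An `mpc_phase_model`.
#' @param term Coefficient name (e.g. `"drug_class4"`, `"travel_class>=10"`).
#' @return A one-row data frame: odds ratio, Wald 95% confidence bounds and
#'   two-sided Wald p-value.
#' @export
adjusted_or <- function(model, term) {
  i <- match(term, names(model$coefficients))
  if (is.na(i)) stop("term not in model: ", term)
  b <- model$coefficients[i]
  s <- model$se[i]
  z <- b / s
  data.frame(term = term, or = exp(b),
             ci_low = exp(b - 1.959964 * s), ci_high = exp(b + 1.959964 * s),
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
}

# One forward-backward stepwise pass with likelihood-ratio entry/removal
# tests; whole terms (all factor levels) enter and leave together.
stepwise_logistic <- function(data, outcome, forced, candidates, alpha) {
  dev_of <- function(terms) {
    f <- phase_formula(outcome, if (length(terms)) terms else "1")
    suppressWarnings(stats::glm(f, data = data,
                                family = stats::binomial()))$deviance
  }
  df_of <- function(term) {
    x <- data[[term]]
    if (is.factor(x)) max(1L, nlevels(droplevels(x)) - 1L) else 1L
  }
  current <- character(0)
  base_dev <- dev_of(forced)
  repeat {
    changed <- FALSE
    # forward
    outside <- setdiff(candidates, current)
    if (length(outside)) {
      ps <- vapply(outside, function(tm) {
        d1 <- dev_of(c(forced, current, tm))
        stats::pchisq(base_dev - d1, df_of(tm), lower.tail = FALSE)
      }, numeric(1))
      if (min(ps) < alpha) {
        tm <- outside[which.min(ps)]
        current <- c(current, tm)
        base_dev <- dev_of(c(forced, current))
        changed <- TRUE
      }
    }
    # backward
    if (length(current)) {
      ps <- vapply(current, function(tm) {
        d0 <- dev_of(c(forced, setdiff(current, tm)))
        stats::pchisq(d0 - base_dev, df_of(tm), lower.tail = FALSE)
      }, numeric(1))
      if (max(ps) >= alpha) {
        current <- setdiff(current, current[which.max(ps)])
        base_dev <- dev_of(c(forced, current))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  current
}

#' Bootstrap stepwise covariate selection
#'
#' Draws `n_bootstrap` with-replacement resamples of the data, runs a
#' forward-backward stepwise logistic selection (likelihood-ratio entry and
#' removal tests at `alpha`) on each, and retains the candidates selected
#' in at least `inclusion_threshold` of the completed procedures. Forced
#' terms are present in every model and never tested. Resamples with a
#' degenerate (all-0 or all-1) outcome are skipped and counted; more than
#' 10% skipped is an error.
#'
#' @param data Analysis rows for one phase's at-risk set.
#' @param outcome Binary outcome column name.
#' @param candidates Candidate terms (must not overlap the forced terms).
#' @param spec A [selection_spec()].
#' @return A list: `selected` (forced plus retained candidates),
#'   `frequencies` (per-candidate inclusion frequency), `n_skipped`.
#' @export
bootstrap_stepwise <- function(data, outcome, candidates,
                               spec = selection_spec()) {
  stopifnot(!any(candidates %in% spec$forced_terms))
  y <- data[[outcome]]
  stopifnot(all(y %in% c(TRUE, FALSE, 0, 1)))
  set.seed(spec$seed)
  counts <- stats::setNames(numeric(length(candidates)), candidates)
  done <- 0L
  skipped <- 0L
  for (b in seq_len(spec$n_bootstrap)) {
    i <- sample.int(nrow(data), nrow(data), replace = TRUE)
    if (length(unique(as.integer(y[i]))) < 2L) {
      skipped <- skipped + 1L
      next
    }
    sel <- stepwise_logistic(data[i, , drop = FALSE], outcome,
                             spec$forced_terms, candidates, spec$alpha)
    counts[sel] <- counts[sel] + 1
    done <- done + 1L
  }
  if (skipped > 0.10 * spec$n_bootstrap) {
    stop("more than 10% of bootstrap resamples had a degenerate outcome (",
         skipped, " of ", spec$n_bootstrap, ")")
  }
  if (skipped > 0L) {
    warning(skipped, " degenerate bootstrap resample(s) skipped")
  }
  freq <- counts / max(done, 1L)
  list(selected = c(spec$forced_terms,
                    candidates[freq >= spec$inclusion_threshold]),
       frequencies = freq, n_skipped = skipped)
}

#' Fit the three phase models on an analysis cohort
#'
#' Fits the emergency model (ordinary logistic, full cohort), the acute
#' model (random-intercept logistic among STEMI admissions) and the
#' post-acute model (random-intercept logistic on the post-acute analysis
#' set). By default all adjustment covariates enter (the full adjustment
#' set); with `select = TRUE` the non-forced covariates are screened per
#' phase by [bootstrap_stepwise()] on ordinary logistic models, and the
#' random intercept is added only at the final fit. Phase exposures are
#' always included.
#'
#' @param rows Analysis table with exposures attached
#'   ([classify_exposures()]).
#' @param select Run bootstrap stepwise covariate selection first?
#' @param sspec A [selection_spec()] (used when `select = TRUE`).
#' @param nAGQ Integration order for the multilevel fits.
#' @return Named list of three `mpc_phase_model` objects
#'   (`emergency`, `acute`, `postacute`), with each phase's selection
#'   report attached as attribute `"selection"` when selection is run.
#' @export
fit_phase_models <- function(rows, select = FALSE, sspec = selection_spec(),
                             nAGQ = 1L) {
  at_risk <- list(
    emergency = rows,
    acute = rows[rows$stemi %in% TRUE, , drop = FALSE],
    postacute = rows[rows$postacute %in% TRUE, , drop = FALSE]
  )
  sel_reports <- list()
  models <- list()
  for (phase in names(at_risk)) {
    d <- droplevels_preserving(at_risk[[phase]])
    expo <- phase_exposure_terms(phase)
    covs <- setdiff(adjustment_terms(), sspec$forced_terms)
    if (select) {
      sp <- sspec
      sp$forced_terms <- c(sspec$forced_terms, expo)
      sp$seed <- derive_seed(sspec$seed, phase)
      rep_ <- bootstrap_stepwise(d, phase_outcome_var(phase), covs, sp)
      terms <- rep_$selected
      sel_reports[[phase]] <- rep_
    } else {
      terms <- c(sspec$forced_terms, covs, expo)
    }
    terms <- unique(c(terms, expo))
    models[[phase]] <- if (phase == "emergency") {
      fit_logistic(d, phase_outcome_var(phase), terms, phase)
    } else {
      fit_multilevel_logistic(d, phase_outcome_var(phase), terms,
                              nAGQ = nAGQ, phase = phase)
    }
  }
  if (select) attr(models, "selection") <- sel_reports
  models
}

# keep factor levels intact (scenario levels must stay in the coding even
# if unobserved in a subset)
droplevels_preserving <- function(d) d

#' Serialize a phase model to JSON
#'
#' Writes terms, coefficients, standard errors, random-intercept standard
#' deviation and fit diagnostics (not the fitted object itself).
#'
#' @param model An `mpc_phase_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phase_model <- function(model, path) {
  x <- model[c("phase", "outcome", "terms", "coefficients", "se", "re_sd",
               "cluster", "loglik", "converged", "n")]
  x$coefficients <- as.list(x$coefficients)
  x$se <- as.list(stats::setNames(x$se, names(model$coefficients)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
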