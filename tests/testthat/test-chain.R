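test_that("chaining multiplies the three conditional survival probabilities", {
  expect_identical(chain(1, 1, 1), 1)
  expect_identical(chain(0.5, 0, 0.9), 0)
  expect_equal(chain(0.724, 0.889, 0.946), 0.6089, tolerance = 5e-5)
  expect_error(chain(1.2, 0.5, 0.5), "0, 1")
  expect_error(chain(0.5, -0.1, 0.5), "0, 1")
  # never exceeds any argument
  set.seed(2)
  for (i in 1:50) {
    p <- runif(3)
    expect_lte(chain(p[1], p[2], p[3]), min(p))
  }
})

test_that("standardization reduces to the intercept for covariate-free models", {
  d <- data.frame(y = rep(c(TRUE, FALSE), 50),
                  travel_class = factor(rep(c("<10", ">=10"), 50),
                                        levels = c("<10", ">=10")))
  m <- fit_logistic(d, "y", "1")
  expect_equal(standardized_probability(m, d, list(travel_class = "<10")), 0.5,
               tolerance = 1e-9)
})

test_that("a zero exposure coefficient makes every scenario identical", {
  m <- exact_travel_model(0.6, 0.6)
  pop <- data.frame(travel_class = factor(rep(c("<10", ">=10"), 30),
                                          levels = c("<10", ">=10")))
  p_a <- standardized_probability(m, pop, list(travel_class = "<10"))
  p_b <- standardized_probability(m, pop, list(travel_class = ">=10"))
  expect_equal(p_a, p_b, tolerance = 1e-9)
})

test_that("scenario levels missing from the model coding raise an error", {
  m <- exact_travel_model(0.6, 0.5)
  pop <- data.frame(travel_class = factor("<10", levels = c("<10", ">=10")))
  expect_error(standardized_probability(m, pop, list(travel_class = "<99")),
               "absent from coding")
})

test_that("standardization equals the brute-force row-wise oracle", {
  rows <- small_cohort()
  models <- .fixtures$small_models
  if (is.null(models)) {
    models <- fit_phase_models(small_cohort())
    .fixtures$small_models <- models
  }
  best <- best_scenario()

  # independent oracle: explicit model-matrix algebra plus direct
  # Gauss-Hermite sum, no predict() involved
  oracle <- function(model, pop, scenario) {
    for (nm in intersect(names(scenario), model$terms)) {
      pop[[nm]] <- factor(scenario[[nm]], levels = levels(rows[[nm]]))
    }
    f <- stats::as.formula(paste("~", paste(model$terms, collapse = "+")))
    X <- stats::model.matrix(f, pop)
    eta <- drop(X %*% model$coefficients[colnames(X)])
    if (is.na(model$re_sd) || model$re_sd == 0) return(mean(plogis(eta)))
    gh <- lme4::GHrule(21L)
    mean(rowSums(vapply(seq_len(nrow(gh)), function(k) {
      gh[k, "w"] * plogis(eta + model$re_sd * gh[k, "z"])
    }, numeric(length(eta)))))
  }
  expect_equal(standardized_probability(models$emergency, rows, best),
               oracle(models$emergency, rows, best), tolerance = 1e-10)
  expect_equal(standardized_probability(models$acute, rows, best),
               oracle(models$acute, rows, best), tolerance = 1e-10)
  expect_equal(standardized_probability(models$postacute, rows, best),
               oracle(models$postacute, rows, best), tolerance = 1e-10)
  # the travel contrast in the emergency phase matches the oracle difference
  worst <- worst_scenario()
  d_pkg <- standardized_probability(models$emergency, rows, best) -
    standardized_probability(models$emergency, rows, worst)
  d_or <- oracle(models$emergency, rows, best) -
    oracle(models$emergency, rows, worst)
  expect_equal(d_pkg, d_or, tolerance = 1e-10)
})

test_that("probability ratios are exact for identity contrasts and reciprocal", {
  rows <- small_cohort()
  models <- .fixtures$small_models %||% fit_phase_models(rows)
  .fixtures$small_models <- models
  best <- best_scenario()
  worst <- worst_scenario()
  expect_identical(scenario_pr(models, rows, best, best)$pr, 1)
  ab <- scenario_pr(models, rows, best, worst)$pr
  ba <- scenario_pr(models, rows, worst, best)$pr
  expect_equal(ab * ba, 1, tolerance = 1e-12)
  expect_gt(ab, 0)
})

test_that("the full scenario table is coherent", {
  rows <- small_cohort()
  models <- .fixtures$small_models %||% fit_phase_models(rows)
  .fixtures$small_models <- models
  tab <- scenario_table(models, rows)
  expect_identical(nrow(tab), 18L)
  expect_true(all(tab$p_overall >= 0 & tab$p_overall <= 1))
  expect_true(all(tab$p_overall <= pmin(tab$p1, tab$p2, tab$p3) + 1e-12))
  # the scenario invariances: p1 ignores hospital and drug class
  expect_equal(length(unique(round(tab$p1[tab$travel_class == "<10"], 12))), 1L)
})

test_that("lower-baseline strata amplify the probability ratio", {
  # two-stratum analytic toy: same exposure log odds ratio, different
  # baseline survival; the ratio of standardized probabilities is larger
  # where baseline survival is lower
  beta <- log(2)
  pr_of <- function(alpha) plogis(alpha + beta) / plogis(alpha)
  expect_gt(pr_of(qlogis(0.3)), pr_of(qlogis(0.9)))
  expect_gt(pr_of(qlogis(0.1)), pr_of(qlogis(0.3)))
})

test_that("lives saved matches the closed-form single-phase expectation", {
  # 100 patients all observed at the worst travel level; worst-level survival
  # 0.5 and an exposure odds ratio of 2 give 100 * (2/3 - 1/2) extra survivors
  m <- exact_travel_model(2 / 3, 1 / 2, n_per = 600L)
  rows <- data.frame(
    travel_class = factor(">=10", levels = c("<10", ">=10"))[rep(1, 100)],
    hosp_class = factor(NA_character_, levels = c("medium", "high", "low")),
    drug_class = factor(NA_character_, levels = c("<=2", "3", "4")),
    stemi = FALSE, postacute = FALSE)
  models <- list(emergency = m, acute = m, postacute = m)
  expect_equal(lives_saved(models, rows), 100 * (2 / 3 - 1 / 2),
               tolerance = 1e-10)
})

test_that("lives saved vanishes with null exposures or empty worst sets", {
  m0 <- exact_travel_model(0.6, 0.6)
  rows_best <- data.frame(
    travel_class = factor("<10", levels = c("<10", ">=10"))[rep(1, 50)],
    hosp_class = factor(NA_character_, levels = c("medium", "high", "low")),
    drug_class = factor(NA_character_, levels = c("<=2", "3", "4")),
    stemi = FALSE, postacute = FALSE)
  models <- list(emergency = m0, acute = m0, postacute = m0)
  expect_identical(lives_saved(models, rows_best), 0)   # nobody at worst level
  rows_worst <- rows_best
  rows_worst$travel_class[] <- ">=10"
  expect_equal(lives_saved(models, rows_worst), 0, tolerance = 1e-10)
})

test_that("degenerate bootstrap gives a zero-width interval at the point", {
  d <- data.frame(x = 1:40)
  ci <- bootstrap_pr_ci(function(d) 1.25, d, n_bootstrap = 50L, seed = 9L)
  expect_identical(ci$pr, 1.25)
  expect_identical(ci$bci_low, 1.25)
  expect_identical(ci$bci_high, 1.25)
  # failure rate above 10% among the resample fits is an error (the
  # full-data point estimate itself succeeds)
  k <- 0L
  flaky <- function(d) {
    k <<- k + 1L
    if (k > 1L && k %% 2L == 0L) stop("boom")
    1
  }
  expect_error(bootstrap_pr_ci(flaky, d, n_bootstrap = 40L, seed = 2L),
               "failed")
})

test_that("null-exposure models give unit subgroup PRs everywhere", {
  rows <- small_cohort()
  m0 <- exact_travel_model(0.6, 0.6)
  models <- list(emergency = m0, acute = m0, postacute = m0)
  for (sg in c("sex", "age_class", "diabetes", "copd")) {
    res <- subgroup_prs(models, rows, sg)
    expect_true(all(abs(res$pr - 1) < 1e-9))
  }
  # tiny strata are skipped with a warning
  rows$rare <- factor(c("r", rep("common", nrow(rows) - 1)))
  expect_warning(res <- subgroup_prs(models, rows, "rare", min_rows = 50L),
                 "skipped")
  expect_identical(res$level, "common")
})
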