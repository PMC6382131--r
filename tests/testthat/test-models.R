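test_that("intercept-only fit equals the closed-form Bernoulli MLE", {
  d <- data.frame(y = rep(c(TRUE, FALSE), c(724, 276)))
  m <- fit_logistic(d, "y", "1")
  expect_equal(unname(m$coefficients[["(Intercept)"]]), qlogis(0.724),
               tolerance = 1e-8)
})

test_that("null covariates estimate near zero, signal covariates recover", {
  set.seed(31)
  n <- 6000
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- runif(n) < plogis(0.3 + 0.8 * d$x)      # z has no effect
  m <- fit_logistic(d, "y", c("x", "z"))
  expect_lt(abs(m$coefficients[["z"]]), 3 * m$se[["z"]])
  expect_lt(abs(m$coefficients[["x"]] - 0.8), 3 * m$se[["x"]])
})

test_that("rank deficiency and separation raise informative errors", {
  d <- data.frame(y = rep(c(TRUE, FALSE), 20), x = rnorm(40))
  d$x2 <- d$x
  expect_error(fit_logistic(d, "y", c("x", "x2")), "aliased")
  d2 <- data.frame(y = rep(c(TRUE, FALSE), each = 20),
                   s = rep(c(1, 0), each = 20))
  expect_error(fit_logistic(d2, "y", "s"), "separation")
})

test_that("adjusted odds ratios use exact Wald arithmetic", {
  m <- exact_travel_model(0.5, 0.5)
  fake <- m
  fake$coefficients <- c("(Intercept)" = 0, x = 0)
  fake$se <- c(0.2, 0.1)
  or <- adjusted_or(fake, "x")
  expect_equal(or$or, 1)
  expect_equal(or$ci_low, exp(-1.959964 * 0.1), tolerance = 1e-9)
  expect_equal(or$ci_high, exp(1.959964 * 0.1), tolerance = 1e-9)
  expect_equal(or$p, 1)
  fake$coefficients[["x"]] <- log(2.62)
  expect_equal(adjusted_or(fake, "x")$or, 2.62, tolerance = 1e-12)
  expect_true(or$ci_low <= or$or && or$or <= or$ci_high)
  expect_error(adjusted_or(m, "nope"), "not in model")
})

test_that("adding a term never lowers the maximized log-likelihood", {
  set.seed(7)
  n <- 800
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- runif(n) < plogis(0.5 * d$a)
  ll <- numeric(3)
  for (k in 1:3) {
    ll[k] <- fit_logistic(d, "y", c("a", "b", "c")[seq_len(k)])$loglik
  }
  expect_true(all(diff(ll) >= -1e-8))
})

simulate_clustered <- function(n_clusters, per_cluster, sd, beta_x = 0.7,
                               seed = 5) {
  set.seed(seed)
  u <- rnorm(n_clusters, 0, sd)
  g <- rep(seq_len(n_clusters), each = per_cluster)
  d <- data.frame(hospital_id = sprintf("H%02d", g), x = rnorm(n_clusters * per_cluster))
  d$y <- runif(nrow(d)) < plogis(0.4 + beta_x * d$x + u[g])
  d
}

test_that("multilevel fit degenerates gracefully when clusters carry no variance", {
  d <- simulate_clustered(30, 150, sd = 0)
  ml <- fit_multilevel_logistic(d, "y", "x")
  gl <- fit_logistic(d, "y", "x")
  expect_lt(ml$re_sd^2, 0.01)
  expect_equal(unname(ml$coefficients[["x"]]), unname(gl$coefficients[["x"]]),
               tolerance = 1e-2)
})

test_that("multilevel fit recovers the random-intercept scale", {
  d <- simulate_clustered(50, 200, sd = 0.5)
  ml <- fit_multilevel_logistic(d, "y", "x")
  expect_gt(ml$re_sd, 0.35)
  expect_lt(ml$re_sd, 0.65)
  expect_lt(abs(ml$coefficients[["x"]] - 0.7), 3 * ml$se[["x"]])
})

test_that("a single cluster falls back to the ordinary fit with a warning", {
  d <- simulate_clustered(1, 300, sd = 0)
  expect_warning(m <- fit_multilevel_logistic(d, "y", "x"), "single|fewer")
  expect_true(is.na(m$re_sd))
})

test_that("bootstrap stepwise keeps true predictors and rejects pure noise", {
  set.seed(88)
  n <- 2000
  d <- data.frame(strong = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n), n4 = rnorm(n), n5 = rnorm(n),
                  sex = factor(sample(c("M", "F"), n, TRUE)),
                  age_class = factor(sample(c("<65", "65+"), n, TRUE)))
  d$y <- runif(n) < plogis(-0.3 + log(3) * d$strong)
  spec <- selection_spec(n_bootstrap = 100L, seed = 12L)
  res <- bootstrap_stepwise(d, "y", c("strong", paste0("n", 1:5)), spec)
  expect_true("strong" %in% res$selected)
  expect_true(all(res$frequencies[paste0("n", 1:5)] < 0.5))
  expect_true(all(c("sex", "age_class") %in% res$selected))
  # deterministic under the seed
  res2 <- bootstrap_stepwise(d, "y", c("strong", paste0("n", 1:5)), spec)
  expect_identical(res$frequencies, res2$frequencies)
  # empty candidate set returns the forced terms only
  res0 <- bootstrap_stepwise(d, "y", character(0),
                             selection_spec(n_bootstrap = 5L, seed = 1L))
  expect_identical(res0$selected, c("sex", "age_class"))
})

test_that("degenerate bootstrap outcomes are skipped, and error past 10%", {
  d <- data.frame(y = rep(c(TRUE, FALSE), c(199, 1)), x = rnorm(200),
                  sex = factor(rep(c("M", "F"), 100)),
                  age_class = factor(rep(c("<65", "65+"), 100)))
  spec <- selection_spec(n_bootstrap = 40L, seed = 3L)
  expect_error(bootstrap_stepwise(d, "y", "x", spec), "degenerate")
})

test_that("selection is stable across seeds with a dominant predictor", {
  set.seed(21)
  n <- 1500
  d <- data.frame(strong = rnorm(n), noise = rnorm(n),
                  sex = factor(sample(c("M", "F"), n, TRUE)),
                  age_class = factor(sample(c("<65", "65+"), n, TRUE)))
  d$y <- runif(n) < plogis(2 * d$strong)
  sel <- lapply(c(1L, 2L, 3L), function(s) {
    bootstrap_stepwise(d, "y", c("strong", "noise"),
                       selection_spec(n_bootstrap = 100L, seed = s))$selected
  })
  expect_identical(sel[[1]], sel[[2]])
  expect_identical(sel[[2]], sel[[3]])
})

test_that("the phase-model wrapper runs the selection path end to end", {
  rows <- small_cohort()
  sp <- selection_spec(n_bootstrap = 5L, seed = 11L)
  models <- suppressWarnings(fit_phase_models(rows, select = TRUE, sspec = sp))
  sel <- attr(models, "selection")
  expect_named(sel, c("emergency", "acute", "postacute"))
  for (ph in names(models)) {
    m <- models[[ph]]
    # forced terms and the phase exposures survive selection unconditionally
    expect_true(all(c("sex", "age_class") %in% m$terms))
    expect_true(all(mpcsurv:::phase_exposure_terms(ph) %in% m$terms))
    # every selected term was a forced term or a screened candidate
    expect_true(all(m$terms %in% c("sex", "age_class",
                                   mpcsurv:::phase_exposure_terms(ph),
                                   names(sel[[ph]]$frequencies))))
    expect_true(all(sel[[ph]]$frequencies >= 0 & sel[[ph]]$frequencies <= 1))
  }
  # multilevel structure retained at the final fits
  expect_false(is.na(models$acute$re_sd))
  expect_false(is.na(models$postacute$re_sd))
})
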