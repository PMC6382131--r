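# Internal helpers shared across modules.

# Deterministic sub-stream seeds: one global seed drives every stage, so a
# stage can be re-run in isolation and still reproduce the pipeline's draws.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Solve mean(plogis(alpha + eta)) = target for alpha by monotone root search.
# `eta` is a vector of linear-predictor offsets (covariates, random effects).
solve_marginal_intercept <- function(eta, target, tol = 1e-10, label = "phase") {
  stopifnot(length(eta) >= 1L, is.finite(target), target > 0, target < 1)
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- stats::qlogis(target) - 1
  hi <- stats::qlogis(target) + 1
  for (i in 1:60) {
    if (f(lo) < 0 && f(hi) > 0) break
    if (f(lo) >= 0) lo <- lo - 2
    if (f(hi) <= 0) hi <- hi + 2
    if (i == 60) stop("intercept calibration failed to bracket a root for ", label)
  }
  r <- stats::uniroot(f, c(lo, hi), tol = tol, maxiter = 200L)
  if (abs(r$f.root) > 1e-6) {
    stop("intercept calibration did not converge for ", label)
  }
  r$root
}

# Sample one categorical level per row from fixed shares (names are levels).
sample_levels <- function(n, shares) {
  stopifnot(abs(sum(shares) - 1) < 1e-8, !is.null(names(shares)))
  factor(sample(names(shares), n, replace = TRUE, prob = shares),
         levels = names(shares))
}

as_date <- function(x) as.Date(x, format = "%Y-%m-%d")

`%||%` <- function(a, b) if (is.null(a)) b else a
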