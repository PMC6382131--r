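# Orchestration: one call from calibration (or saved tables) to the full
# set of reports, with deterministic per-stage seed substreams.

#' Run the full multicomponent process-of-care pipeline
#'
#' Executes simulate (optional) -> build cohort -> classify exposures ->
#' fit phase models -> scenario standardization, best-vs-worst probability
#' ratios, subgroup ratios and lives-saved estimate, writing each product
#' to `out_dir`:
#'
#' * `flow.json`: realized cohort flow counts;
#' * `table1.csv`: per-phase covariate distributions and adjusted odds
#'   ratios with Wald intervals;
#' * `scenarios.csv`: standardized survival for all 18 scenarios;
#' * `prs.csv`: overall and subgroup best-vs-worst probability ratios
#'   (with bootstrap intervals when `n_bootstrap > 0`);
#' * `model_<phase>.json`: serialized phase models;
#' * `manifest.json`: seed, configuration checksum, package and R versions,
#'   output list.
#'
#' Identical configuration and seed yield identical outputs.
#'
#' @param config An [mpc_calibration][new_calibration] object (simulate a
#'   registry), or `NULL` when `input_dir` is given.
#' @param input_dir Directory of registry CSVs from [write_registry()].
#' @param seed Global integer seed; per-stage substreams are derived from it.
#' @param out_dir Output directory (created if needed).
#' @param n_bootstrap Bootstrap resamples for the PR confidence interval
#'   (0 skips the interval).
#' @param subgroups Stratifier columns for subgroup PRs.
#' @param select Run bootstrap stepwise covariate selection before the
#'   final fits (otherwise the full adjustment set is used).
#' @param sspec A [selection_spec()] for the selection stage.
#' @param verbose Emit progress messages to stderr.
#' @return Invisibly, a list with the bundle, cohort rows, models, scenario
#'   table, PR results and manifest.
#' @export
run_pipeline <- function(config = NULL, input_dir = NULL, seed = 20110101L,
                         out_dir = tempfile("mpc_run_"), n_bootstrap = 0L,
                         subgroups = c("sex", "age_class", "diabetes", "copd"),
                         select = FALSE, sspec = selection_spec(),
                         verbose = TRUE) {
  if (is.null(config) == is.null(input_dir)) {
    stop("provide exactly one of `config` (simulate) or `input_dir` (load)")
  }
  say <- function(...) if (verbose) message("[mpcsurv] ", ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(config)) {
    say("simulating registry (n = ", config$n_patients, ")")
    bundle <- generate_registry(config, seed = derive_seed(seed, "simulate"))
  } else {
    say("reading registry from ", input_dir)
    bundle <- read_registry(input_dir)
  }

  say("building cohort")
  rows <- build_cohort(bundle)
  rows <- classify_exposures(rows, bundle)
  flow <- attr(rows, "flow") %||% cohort_flow(rows)
  jsonlite::write_json(flow, file.path(out_dir, "flow.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("fitting phase models", if (select) " (with bootstrap stepwise selection)")
  sspec$seed <- derive_seed(seed, "selection")
  models <- fit_phase_models(rows, select = select, sspec = sspec)
  for (ph in names(models)) {
    write_phase_model(models[[ph]], file.path(out_dir,
                                              paste0("model_", ph, ".json")))
  }
  utils::write.csv(table1_report(models, rows),
                   file.path(out_dir, "table1.csv"), row.names = FALSE)

  say("standardizing scenarios")
  scen <- scenario_table(models, phase_populations(rows))
  utils::write.csv(scen, file.path(out_dir, "scenarios.csv"), row.names = FALSE)

  best <- best_scenario()
  worst <- worst_scenario()
  overall <- scenario_pr(models, phase_populations(rows), best, worst)
  pr_rows <- data.frame(stratifier = "overall", level = "all", n = nrow(rows),
                        p_best = overall$scenario_a$p_overall,
                        p_worst = overall$scenario_b$p_overall,
                        pr = overall$pr, stringsAsFactors = FALSE)
  for (sg in subgroups) {
    pr_rows <- rbind(pr_rows, subgroup_prs(models, rows, sg))
  }
  ci <- NULL
  if (n_bootstrap > 0) {
    say("bootstrapping the PR interval (B = ", n_bootstrap, ")")
    terms <- lapply(models, `[[`, "terms")
    # resample fits can be rough (small strata, boundary variance); their
    # diagnostics are expected noise inside the bootstrap loop
    refit_pr <- function(d) suppressWarnings({
      m <- list(
        emergency = fit_logistic(d, "survived_emergency", terms$emergency,
                                 "emergency"),
        acute = fit_multilevel_logistic(d[d$stemi %in% TRUE, , drop = FALSE],
                                        "survived_30d", terms$acute,
                                        phase = "acute"),
        postacute = fit_multilevel_logistic(
          d[d$postacute %in% TRUE, , drop = FALSE], "survived_31_365",
          terms$postacute, phase = "postacute")
      )
      scenario_pr(m, phase_populations(d), best, worst)$pr
    })
    ci <- bootstrap_pr_ci(refit_pr, rows, n_bootstrap = n_bootstrap,
                          seed = derive_seed(seed, "pr_ci"))
    pr_rows$bci_low <- c(ci$bci_low, rep(NA, nrow(pr_rows) - 1L))
    pr_rows$bci_high <- c(ci$bci_high, rep(NA, nrow(pr_rows) - 1L))
  }
  utils::write.csv(pr_rows, file.path(out_dir, "prs.csv"), row.names = FALSE)

  saved <- lives_saved(models, rows)

  cfg_path <- file.path(out_dir, "calibration.yaml")
  if (!is.null(config)) write_calibration(config, cfg_path)
  outputs <- c("flow.json", "table1.csv", "scenarios.csv", "prs.csv",
               paste0("model_", names(models), ".json"))
  manifest <- list(
    seed = seed,
    config_md5 = if (file.exists(cfg_path))
      unname(tools::md5sum(cfg_path)) else NA,
    package_version = as.character(utils::packageVersion("mpcsurv")),
    r_version = R.version.string,
    n_index = flow$n_index,
    lives_saved_best_vs_worst = saved,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; outputs in ", out_dir)
  invisible(list(bundle = bundle, rows = rows, models = models,
                 scenarios = scen, prs = pr_rows, pr_ci = ci,
                 lives_saved = saved, manifest = manifest,
                 out_dir = out_dir))
}

#' Per-phase covariate distribution and adjusted odds-ratio report
#'
#' For each phase model: the distribution (%) of every model covariate in
#' that phase's at-risk set, with the adjusted odds ratio, Wald 95%
#' interval and p-value of each non-reference coefficient.
#'
#' @param models Named list of the three phase models.
#' @param rows Analysis table the models were fitted on.
#' @return A long-format data frame.
#' @export
table1_report <- function(models, rows) {
  at_risk <- list(
    emergency = rows,
    acute = rows[rows$stemi %in% TRUE, , drop = FALSE],
    postacute = rows[rows$postacute %in% TRUE, , drop = FALSE]
  )
  out <- list()
  for (ph in names(models)) {
    m <- models[[ph]]
    d <- at_risk[[ph]]
    for (tm in m$terms) {
      x <- d[[tm]]
      if (is.factor(x)) {
        for (lv in levels(x)) {
          cname <- paste0(tm, lv)
          stat <- if (cname %in% names(m$coefficients)) {
            adjusted_or(m, cname)
          } else {
            data.frame(term = cname, or = 1, ci_low = NA, ci_high = NA, p = NA)
          }
          out[[length(out) + 1L]] <- data.frame(
            phase = ph, variable = tm, level = lv,
            pct = 100 * mean(x == lv, na.rm = TRUE),
            or = stat$or, ci_low = stat$ci_low, ci_high = stat$ci_high,
            p = stat$p, stringsAsFactors = FALSE)
        }
      } else {
        cname <- if (paste0(tm, "TRUE") %in% names(m$coefficients)) {
          paste0(tm, "TRUE")
        } else tm
        stat <- if (cname %in% names(m$coefficients)) adjusted_or(m, cname) else
          data.frame(term = cname, or = NA, ci_low = NA, ci_high = NA, p = NA)
        out[[length(out) + 1L]] <- data.frame(
          phase = ph, variable = tm, level = "yes",
          pct = 100 * mean(x %in% TRUE),
          or = stat$or, ci_low = stat$ci_low, ci_high = stat$ci_high,
          p = stat$p, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
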