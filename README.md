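# mpcsurv

Survival after acute myocardial infarction (AMI) is decided three times:
on the way to the hospital, in the hospital, and in the year after
discharge. `mpcsurv` implements a reusable pipeline for studying this
**multicomponent process of care (MPC)** with linked administrative
health data — hospital admissions (ICD-9-CM), drug dispensings (ATC) and
cause-specific mortality — of the kind held by regional health
information systems. It is written for epidemiologists and health-services
researchers who want to quantify how much the *whole* care pathway, not a
single phase, moves 1-year survival.

## The model

One-year survival is decomposed into three chained conditional
probabilities,

```
P(survive 1 year) = p1 · p2 · p3
```

* `p1` — probability of reaching the hospital alive (emergency phase),
* `p2` — 30-day survival from admission, given `p1`, among STEMI
  admissions (acute phase),
* `p3` — survival over days 31–365 from discharge, given `p2`
  (post-acute phase),

each fitted by logistic regression on demographics, chronic conditions,
2-year comorbidity and 6-month co-medication lookbacks, plus one
phase-specific quality-of-care exposure: travel time (`<10` vs `>=10`
minutes), hospital PCI performance class (`high`/`medium`/`low` by a
two-indicator quartile rule), and the count of distinct evidence-based
drug classes dispensed within 30 days of discharge (`<=2`/`3`/`4`).
The acute and post-acute models carry a hospital random intercept
(`lme4`). Covariates can be screened by the bootstrap stepwise rule
(1000 resamples, p = 0.05, keep factors selected in ≥50%).

Scenario contrasts use g-computation: each phase's fitted probabilities
are averaged over that phase's analysis cohort with the exposures pinned
to a scenario — a *mean-severity* patient. The headline quantity is the
probability ratio (PR) of chained survival under the best scenario
(`<10`, `high`, `4`) versus the worst (`>=10`, `low`, `<=2`), with
percentile bootstrap intervals, subgroup PRs and an expected
lives-saved estimate.

Because no registry extract can be redistributed, the package ships a
calibrated synthetic registry generator: `generate_registry()` emits the
five linked tables (patients, admissions, prescriptions, deaths,
hospitals) with cohort flow, covariate and exposure distributions and
effect sizes matching the published figures for incident AMI in a large
Italian region, 2011–2014 (38,517 cases; phase survival 72.4% / 88.9% /
94.6%). Every downstream stage is tested against it.

## Worked example

```r
library(mpcsurv)

cfg    <- default_calibration()                 # published marginals & ORs
bundle <- generate_registry(cfg, seed = 20110101)
rows   <- classify_exposures(build_cohort(bundle), bundle)
unlist(cohort_flow(rows)[7:9])
#>  p_reached_alive   p_survived_30d p_survived_31_365
#>           0.7193           0.8902            0.9503

models <- fit_phase_models(rows)                # full adjustment set
adjusted_or(models$emergency, "travel_class>=10")$or   #> 0.909
adjusted_or(models$postacute, "drug_class4")$or        #> 2.128

pops <- phase_populations(rows)
scenario_pr(models, pops, best_scenario(), worst_scenario())$pr
#> 1.207
subgroup_prs(models, rows, "age_class")[, c("level", "pr")]
#>   level    pr      (ages <65 ... 85+)
#>   <65    1.067
#>   ...
#>   85+    1.734
```

Reading: the simulated cohort reproduces the three phase survival
fractions to a few tenths of a percentage point; the fitted travel-time
odds ratio (0.91) recovers the calibrated 0.90; and a mean-severity
patient under the best care scenario has a 21% higher 1-year survival
probability than under the worst — rising to ~73% higher among patients
over 85, because relative survival gains amplify where baseline survival
is low. Model-fit quantities (ORs, PRs) carry the sampling noise of a
cohort this size; a different seed moves them within their standard
errors.

`run_pipeline(config = default_calibration(), seed = 1, out_dir = "out")`
executes the whole chain and writes the cohort-flow JSON, an adjusted-OR
table, the 18-scenario table and the PR table, plus a run manifest. A
thin command-line wrapper with `simulate`, `build-cohort` and `run-all`
subcommands is installed at `inst/cli/mpcsurv.R`.

## Layout

```
R/                 calibration, generator, cohort builder, exposures,
                   phase models, survival chain, pipeline
tests/testthat/    unit + property + end-to-end suites
scripts/           acceptance script
vignettes/         methods vignette (model, calibration, conventions)
inst/cli/          command-line wrapper
```
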