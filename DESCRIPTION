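Package: mpcsurv
Title: Multicomponent Process-of-Care Survival Analysis After Acute
    Myocardial Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the whole multicomponent process of care
    (MPC) after acute myocardial infarction relates to 1-year survival.
    The one-year survival probability is decomposed into three chained
    conditional probabilities (reaching hospital alive, 30-day survival
    after admission for STEMI, 31-365-day survival after discharge), each
    modelled by a (multilevel) logistic regression with phase-specific
    quality-of-care exposures: travel time to hospital, hospital PCI
    performance class, and evidence-based drug therapy after discharge.
    Includes a calibrated synthetic health-information-system generator
    producing linked admission, prescription and mortality tables; cohort
    construction with incident-case washout and lookback windows;
    bootstrap stepwise covariate selection; g-computation scenario
    standardization; and best-versus-worst scenario probability ratios
    with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
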