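#' Diagnosis and drug coding maps
#'
#' Code sets used to read the synthetic registry tables: ICD-9-CM diagnosis
#' codes defining the index AMI event and the chronic-condition lookback
#' flags, and ATC prefixes defining the prior-drug (co-medication) groups
#' evaluated in the 6 months before the index event. Matching is by code
#' prefix throughout.
#'
#' @format Named lists of character prefix vectors.
#' @name coding_maps
NULL

#' @rdname coding_maps
#' @export
icd9_ami_prefix <- "410"

#' @rdname coding_maps
#' @export
icd9_ischemic_death_prefixes <- c("410", "411", "412", "413", "414")

#' @rdname coding_maps
#' @export
icd9_comorbidity_codes <- list(
  cancer        = c("153", "162", "174", "185", "200"),
  hypertension  = c("401", "402", "403", "404", "405"),
  heart_failure = "428",
  arrhythmia    = "427",
  prior_pci     = "V4582",
  other_ihd     = c("411", "412", "413", "414"),
  nephropathy   = c("585", "586")
)

#' @rdname coding_maps
#' @export
atc_comed_codes <- list(
  pre_cardiac          = "C01",
  pre_antiplatelet     = "B01AC",
  pre_anticoagulant    = "B01AA",
  pre_antihypertensive = "C02",
  pre_diuretic         = "C03",
  pre_betablocker      = "C07",
  pre_ccb              = "C08",
  pre_acei             = "C09A",
  pre_arb              = "C09C",
  pre_statin           = "C10AA"
)

# prefix matching: does code start with any of the given prefixes?
matches_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}
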