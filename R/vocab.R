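#' endorisk: integrated histomolecular risk classification of endometrial carcinoma
#'
#' Implements the TCGA-surrogate molecular classification of endometrial
#' carcinoma (POLE ultramutated, mismatch-repair deficient, p53 abnormal, no
#' specific molecular profile), prognostic risk stratification under the ESMO
#' 2016 recommendations and the ESGO/ESTRO/ESP 2020 guidelines (with and
#' without molecular data), a histopathologic triage rule that restricts POLE
#' sequencing to cases whose risk class could change, cohort-level migration
#' and disease-free survival statistics, and a seeded synthetic-cohort
#' generator calibrated to a published consecutive cohort of 211 patients.
#'
#' @keywords internal
"_PACKAGE"

## Controlled vocabularies. Every categorical value accepted anywhere in the
## package appears here; free text is rejected at validation.
.vocab <- list(
  histotype = c("endometrioid", "serous", "clear_cell",
                "undifferentiated_dedifferentiated", "carcinosarcoma", "mixed"),
  grade = c("low", "high"),
  myometrial_invasion = c("none", "lt50", "ge50"),
  lvsi = c("absent", "focal", "substantial"),
  lymph_nodes = c("negative", "positive", "unknown"),
  figo_stage = c("IA", "IB", "II", "III", "IVA", "IVB"),
  p53_ihc = c("wildtype", "overexpression", "null_pattern", "cytoplasmic", "not_done"),
  mmr_ihc = c("retained", "lost", "not_done"),
  pole_status = c("pathogenic", "wildtype", "not_tested"),
  mmr_status = c("deficient", "proficient", "not_done"),
  p53_status = c("abnormal", "wildtype", "not_done"),
  subgroup = c("POLE", "MMRd", "p53abn", "NSMP"),
  risk_class = c("low", "intermediate", "high_intermediate", "high",
                 "advanced_metastatic"),
  system = c("esmo2016", "esgo2020_unknown", "esgo2020_known")
)

#' Cohort table schema
#'
#' Column names (in order) of the per-patient cohort CSV consumed and produced
#' by [read_cohort()] and [write_cohort()].
#'
#' @return Character vector of the 18 column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "age_years", "bmi", "histotype", "grade",
    "myometrial_invasion", "lvsi", "lymph_nodes", "figo_stage",
    "residual_disease", "p53_ihc", "mlh1", "pms2", "msh2", "msh6",
    "pole_status", "dfs_months", "recurrence_event")
}

#' Controlled vocabularies of the cohort schema
#'
#' @return Named list mapping each categorical field to its legal values.
#' @export
cohort_vocabulary <- function() {
  .vocab[c("histotype", "grade", "myometrial_invasion", "lvsi", "lymph_nodes",
           "figo_stage", "p53_ihc", "mmr_ihc", "pole_status")]
}

#' Ordered prognostic risk classes
#'
#' The five-level risk scale shared by the ESMO 2016 and ESGO/ESTRO/ESP 2020
#' systems, from lowest to highest risk. "Lower"/"higher" in migration
#' summaries refers to position on this scale.
#'
#' @return Character vector of length 5.
#' @export
risk_classes <- function() .vocab$risk_class

#' TCGA-surrogate molecular subgroups
#'
#' In hierarchy order: POLE dominates MMRd dominates p53abn; NSMP is the
#' marker-negative remainder.
#'
#' @return Character vector of length 4.
#' @export
molecular_subgroups <- function() .vocab$subgroup

## stages counted as "stage I" by the early-stage rules
.stage_i <- c("IA", "IB")
.stage_advanced <- c("III", "IVA", "IVB")

`%||%` <- function(a, b) if (is.null(a)) b else a
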