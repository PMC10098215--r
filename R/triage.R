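## Histopathologic triage for POLE sequencing.
##
## MMR and p53 immunohistochemistry are performed on every endometrial
## carcinoma; POLE sequencing is restricted to cases whose risk class could
## change with molecular data. Advanced-stage (III/IV) tumors are high risk or
## advanced regardless of subgroup, and clinicopathologic low-risk tumors
## cannot be down-staged further, so both are exempt. Every remaining case
## carries at least one of: non-endometrioid histotype, high grade,
## substantial LVSI, stage IB-II.

#' Triage a cohort for POLE sequencing
#'
#' Vectorized per-patient decision using clinicopathologic fields only.
#'
#' @param cohort Cohort data frame (profiles must be complete).
#' @return Data frame with `patient_id`, `needs_pole_test`, `exemption`
#'   (`advanced_stage` / `low_risk_clinicopathologic` / `none`) and `reasons`
#'   (comma-joined criterion tags among `non_endometrioid`, `high_grade`,
#'   `substantial_lvsi`, `stage_IB_II`; empty when exempt).
#' @export
triage_cohort <- function(cohort) {
  d <- as.data.frame(cohort)
  .check_profiles(d)
  advanced <- d$figo_stage %in% .stage_advanced
  low <- classify_esgo2020(d)$risk_class == "low"
  exemption <- ifelse(advanced, "advanced_stage",
                      ifelse(low, "low_risk_clinicopathologic", "none"))
  crit <- cbind(non_endometrioid = d$histotype != "endometrioid",
                high_grade = d$grade == "high",
                substantial_lvsi = d$lvsi == "substantial",
                stage_IB_II = d$figo_stage %in% c("IB", "II"))
  reasons <- vapply(seq_len(nrow(d)), function(i)
    paste(colnames(crit)[crit[i, ]], collapse = ","), character(1))
  needs <- exemption == "none"
  reasons[!needs] <- ""
  stopifnot(all(!needs | nzchar(reasons)))  # non-exempt always has a criterion
  data.frame(patient_id = as.character(d$patient_id),
             needs_pole_test = needs, exemption = exemption,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Triage a single patient
#'
#' @param patient Named list or one-row data frame of clinicopathologic
#'   fields.
#' @return List with `needs_pole_test`, `exemption`, and `reasons` (character
#'   vector of criterion tags).
#' @export
triage_patient <- function(patient) {
  row <- as.data.frame(as.list(patient), stringsAsFactors = FALSE)
  if (is.null(row$patient_id)) row$patient_id <- "patient"
  if (is.null(row$residual_disease)) row$residual_disease <- FALSE
  t <- triage_cohort(row)
  list(needs_pole_test = t$needs_pole_test,
       exemption = t$exemption,
       reasons = if (nzchar(t$reasons)) strsplit(t$reasons, ",")[[1]]
                 else character(0))
}

#' Evaluate the triage algorithm against full molecular testing
#'
#' Quantifies the sequencing reduction and audits concordance: each patient's
#' 2020 known-mode risk class using the true POLE status is compared with the
#' class obtained when POLE is only sequenced in triaged patients (an untested
#' POLE is assumed wildtype, so the class comes from MMR/p53 alone).
#'
#' @param cohort Cohort data frame with full marker data (every patient's true
#'   POLE status resolvable).
#' @param molecular Optional precomputed [classify_molecular()] table.
#' @param ruleset [pole_ruleset()] used when deriving `molecular`.
#' @return List of class `triage_report`: `n_total`, `n_tested`, `n_spared`,
#'   `n_spared_low_risk`, `n_spared_advanced`, `reduction_fraction`,
#'   `discordant_patients`, plus the per-patient `decisions` table.
#' @export
evaluate_triage <- function(cohort, molecular = NULL,
                            ruleset = pole_ruleset()) {
  d <- as.data.frame(cohort)
  if (is.null(molecular)) molecular <- classify_molecular(d, ruleset = ruleset)
  dec <- triage_cohort(d)

  full <- classify_esgo2020(d, molecular)
  triaged_mol <- molecular
  untested <- !dec$needs_pole_test
  triaged_mol$pole_status[untested] <- "wildtype"   # assumed, not measured
  triaged_mol <- assign_subgroup(triaged_mol$pole_status,
                                 triaged_mol$mmr_status,
                                 triaged_mol$p53_status)
  triaged_mol$patient_id <- molecular$patient_id
  triaged <- classify_esgo2020(d, triaged_mol)

  disc <- dec$patient_id[full$risk_class != triaged$risk_class]
  n <- nrow(d)
  rep <- list(
    n_total = n,
    n_tested = sum(dec$needs_pole_test),
    n_spared = sum(!dec$needs_pole_test),
    n_spared_low_risk = sum(dec$exemption == "low_risk_clinicopathologic"),
    n_spared_advanced = sum(dec$exemption == "advanced_stage"),
    reduction_fraction = sum(!dec$needs_pole_test) / n,
    discordant_patients = disc,
    decisions = dec
  )
  class(rep) <- "triage_report"
  rep
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf(
    "POLE triage: %d/%d tested (%.1f%%), %d spared (%.1f%%) = %d low risk + %d advanced stage\n",
    x$n_tested, x$n_total, 100 * x$n_tested / x$n_total, x$n_spared,
    100 * x$reduction_fraction, x$n_spared_low_risk, x$n_spared_advanced))
  cat(sprintf("discordant risk class vs full testing: %d patient(s)%s\n",
              length(x$discordant_patients),
              if (length(x$discordant_patients) > 0)
                paste0(" [", paste(x$discordant_patients, collapse = ", "), "]")
              else ""))
  invisible(x)
}
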