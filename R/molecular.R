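## Marker interpretation and TCGA-surrogate subgroup assignment.
##
## The diagnostic hierarchy is POLE > MMRd > p53abn > NSMP: POLE sequencing is
## interpreted first, then mismatch-repair IHC, then p53 IHC; a tumor positive
## for two or more markers ("multiple classifier") is resolved by that order.

#' Interpret the p53 immunohistochemical pattern
#'
#' Any of the three aberrant patterns — diffuse overexpression, complete
#' absence ("null"), or cytoplasmic staining — is a mutant-like (abnormal)
#' result, the surrogate for TP53 mutation.
#'
#' @param pattern Character vector over
#'   `wildtype`/`overexpression`/`null_pattern`/`cytoplasmic`/`not_done`.
#' @return Character vector over `abnormal`/`wildtype`/`not_done`.
#' @export
interpret_p53 <- function(pattern) {
  bad <- !(pattern %in% .vocab$p53_ihc)
  if (any(bad)) stop("illegal p53 pattern: ", pattern[bad][1])
  out <- rep("abnormal", length(pattern))
  out[pattern == "wildtype"] <- "wildtype"
  out[pattern == "not_done"] <- "not_done"
  out
}

#' Interpret mismatch-repair protein IHC
#'
#' A tumor is mismatch-repair deficient if any of MLH1, PMS2, MSH2, MSH6 shows
#' loss of nuclear expression (loss of a functional pair MLH1/PMS2 or
#' MSH2/MSH6 is the common pattern, but a single lost protein suffices).
#' All four retained is proficient; an untested protein with no loss elsewhere
#' leaves the status undetermined.
#'
#' @param mlh1,pms2,msh2,msh6 Character vectors over
#'   `retained`/`lost`/`not_done`.
#' @return Character vector over `deficient`/`proficient`/`not_done`.
#' @export
interpret_mmr <- function(mlh1, pms2, msh2, msh6) {
  m <- cbind(mlh1, pms2, msh2, msh6)
  if (!all(m %in% .vocab$mmr_ihc))
    stop("illegal MMR IHC value: ", m[!(m %in% .vocab$mmr_ihc)][1])
  any_lost <- rowSums(m == "lost") > 0
  any_nd <- rowSums(m == "not_done") > 0
  ifelse(any_lost, "deficient", ifelse(any_nd, "not_done", "proficient"))
}

#' Filter variant calls on allele fraction and strand support
#'
#' Retains calls with `vaf >= vaf_min` and, when the ruleset requires
#' both-strand support, at least one alt read on each strand. Order is
#' preserved; the thresholds come from the panel's analytic validity rules,
#' not from pathogenicity.
#'
#' @param variants Data frame in the [read_variants()] layout.
#' @param ruleset A [pole_ruleset()].
#' @return The retained rows of `variants`.
#' @export
filter_variants <- function(variants, ruleset = pole_ruleset()) {
  .check_variants(variants)
  keep <- variants$vaf >= ruleset$vaf_min
  if (ruleset$require_both_strands)
    keep <- keep & variants$reads_forward > 0 & variants$reads_reverse > 0
  variants[keep, , drop = FALSE]
}

#' Call POLE status from filtered variants
#'
#' A tumor is POLE-mutant if any filtered call is in the POLE gene, falls in a
#' covered exonuclease-domain exon, and its protein change is on the
#' pathogenic whitelist. A sequenced tumor with no qualifying call is
#' wildtype; `not_tested` is reserved for tumors never sequenced (pass
#' `tested = FALSE`).
#'
#' @param variants Filtered variant calls for one patient (possibly 0 rows).
#' @param ruleset A [pole_ruleset()].
#' @param tested Was POLE sequencing performed? Default `TRUE`.
#' @return One of `pathogenic`/`wildtype`/`not_tested`.
#' @export
interpret_pole <- function(variants, ruleset = pole_ruleset(), tested = TRUE) {
  if (!tested) return("not_tested")
  if (is.null(variants) || nrow(variants) == 0) return("wildtype")
  pc <- toupper(sub("^p\\.", "", variants$protein_change))
  hit <- toupper(variants$gene) == "POLE" &
    variants$exon %in% ruleset$covered_exons &
    pc %in% ruleset$whitelist
  if (any(hit)) "pathogenic" else "wildtype"
}

#' Assign the TCGA-surrogate molecular subgroup
#'
#' Applies the diagnostic hierarchy POLE > MMRd > p53abn > NSMP to resolved
#' marker statuses and records the full classifier profile so that
#' multiple-classifier tumors stay auditable.
#'
#' @param pole_status `pathogenic`/`wildtype` (vectorized).
#' @param mmr_status `deficient`/`proficient`.
#' @param p53_status `abnormal`/`wildtype`.
#' @return Data frame with columns `pole_status`, `mmr_status`, `p53_status`,
#'   `classifier_profile` (comma-joined positive markers, `""` for NSMP),
#'   `multiple_classifier`, `subgroup`.
#' @examples
#' assign_subgroup("pathogenic", "deficient", "abnormal")  # triple positive -> POLE
#' @export
assign_subgroup <- function(pole_status, mmr_status, p53_status) {
  n <- max(length(pole_status), length(mmr_status), length(p53_status))
  pole_status <- rep_len(pole_status, n)
  mmr_status <- rep_len(mmr_status, n)
  p53_status <- rep_len(p53_status, n)
  unresolved <- pole_status %in% "not_tested" | mmr_status %in% "not_done" |
    p53_status %in% "not_done" | is.na(pole_status) | is.na(mmr_status) |
    is.na(p53_status)
  if (any(unresolved))
    stop("insufficient markers for molecular-known classification (",
         sum(unresolved), " case(s) with POLE not_tested or IHC not_done)")
  if (!all(pole_status %in% c("pathogenic", "wildtype")) ||
      !all(mmr_status %in% c("deficient", "proficient")) ||
      !all(p53_status %in% c("abnormal", "wildtype")))
    stop("illegal marker status passed to assign_subgroup()")

  pos_pole <- pole_status == "pathogenic"
  pos_mmr <- mmr_status == "deficient"
  pos_p53 <- p53_status == "abnormal"
  profile <- vapply(seq_len(n), function(i)
    paste(c("POLE", "MMRd", "p53abn")[c(pos_pole[i], pos_mmr[i], pos_p53[i])],
          collapse = ","), character(1))
  n_pos <- pos_pole + pos_mmr + pos_p53
  subgroup <- ifelse(pos_pole, "POLE",
                     ifelse(pos_mmr, "MMRd",
                            ifelse(pos_p53, "p53abn", "NSMP")))
  data.frame(pole_status = pole_status, mmr_status = mmr_status,
             p53_status = p53_status, classifier_profile = profile,
             multiple_classifier = n_pos >= 2, subgroup = subgroup,
             stringsAsFactors = FALSE)
}

#' Molecularly classify a cohort
#'
#' Resolves p53 and MMR IHC, derives POLE status from the `pole_status` column
#' or, for patients where it is `not_tested`, from supplied variant calls, and
#' assigns every patient a TCGA-surrogate subgroup.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param variants Optional variants table ([read_variants()] /
#'   [read_variants_vcf()]); filtered with `ruleset` before interpretation.
#'   A patient present in `variants` counts as sequenced even if all calls
#'   fail the filter.
#' @param ruleset A [pole_ruleset()].
#' @return Data frame keyed by `patient_id` with the [assign_subgroup()]
#'   columns.
#' @export
classify_molecular <- function(cohort, variants = NULL,
                               ruleset = pole_ruleset()) {
  pole <- as.character(cohort$pole_status)
  if (!is.null(variants) && nrow(variants) > 0) {
    kept <- filter_variants(variants, ruleset)
    for (pid in unique(variants$patient_id)) {
      i <- which(cohort$patient_id == pid & pole == "not_tested")
      if (length(i) > 0)
        pole[i] <- interpret_pole(kept[kept$patient_id == pid, , drop = FALSE],
                                  ruleset)
    }
  }
  call <- assign_subgroup(pole,
                          interpret_mmr(cohort$mlh1, cohort$pms2,
                                        cohort$msh2, cohort$msh6),
                          interpret_p53(cohort$p53_ihc))
  cbind(data.frame(patient_id = as.character(cohort$patient_id),
                   stringsAsFactors = FALSE), call)
}
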