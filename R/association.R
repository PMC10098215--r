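## Association of molecular subgroups with clinicopathologic covariates.

#' Test covariate association with molecular subgroup
#'
#' Categorical covariates are tested with Pearson's chi-square, switching to
#' Fisher's exact test when any expected cell count falls below
#' `fisher_threshold` (both tests are standard for cohort characteristics
#' tables; the switch rule is explicit and configurable). Numeric covariates
#' are tested with the Kruskal-Wallis rank test across the subgroups. All
#' p-values are two-sided.
#'
#' @param cohort Cohort data frame.
#' @param molecular [classify_molecular()] output (or data frame with
#'   `patient_id`, `subgroup`) defining the grouping.
#' @param covariates Columns to test; default the standard cohort covariates.
#'   `lymph_nodes` drops `unknown`, categorical covariates drop single-level
#'   cases with an explanatory note.
#' @param fisher_threshold Expected-cell cutoff for the exact test
#'   (default 5).
#' @return Data frame with `covariate`, `type`, `test`, `statistic`,
#'   `p_value`, `note`.
#' @export
association_tests <- function(cohort, molecular,
                              covariates = c("age_years", "bmi", "histotype",
                                             "grade", "myometrial_invasion",
                                             "lvsi", "lymph_nodes",
                                             "figo_stage"),
                              fisher_threshold = 5) {
  d <- as.data.frame(cohort)
  grp <- molecular$subgroup[match(as.character(d$patient_id),
                                  as.character(molecular$patient_id))]
  if (anyNA(grp)) stop("molecular call missing for some patients")
  grp <- factor(grp, levels = molecular_subgroups())

  one <- function(cov) {
    x <- d[[cov]]
    if (is.null(x)) stop("unknown covariate: ", cov)
    note <- ""
    if (is.numeric(x)) {
      ok <- !is.na(x)
      kw <- stats::kruskal.test(x[ok], droplevels(grp[ok]))
      return(data.frame(covariate = cov, type = "numeric",
                        test = "kruskal_wallis",
                        statistic = unname(kw$statistic),
                        p_value = kw$p.value, note = note,
                        stringsAsFactors = FALSE))
    }
    keep <- !is.na(x) & x != "unknown" & x != "not_done"
    if (!any(keep) || length(unique(x[keep])) < 2)
      return(data.frame(covariate = cov, type = "categorical", test = "none",
                        statistic = NA_real_, p_value = NA_real_,
                        note = "degenerate: fewer than 2 observed categories",
                        stringsAsFactors = FALSE))
    tab <- table(x[keep], droplevels(grp[keep]))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < fisher_threshold)) {
      ft <- tryCatch(stats::fisher.test(tab, workspace = 2e7),
                     error = function(e)
                       stats::fisher.test(tab, simulate.p.value = TRUE,
                                          B = 1e5))
      data.frame(covariate = cov, type = "categorical", test = "fisher",
                 statistic = NA_real_, p_value = ft$p.value,
                 note = sprintf("expected cell < %g", fisher_threshold),
                 stringsAsFactors = FALSE)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      data.frame(covariate = cov, type = "categorical", test = "chisq",
                 statistic = unname(ct$statistic), p_value = ct$p.value,
                 note = note, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(covariates, one))
  rownames(out) <- NULL
  out
}
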