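## Seeded synthetic-cohort generator. Emulates the statistical structure of
## the 211-patient development cohort: subgroup prevalences, per-subgroup
## clinicopathologic distributions, the multiple-classifier rates, marker
## panels consistent with the drawn subgroup, and recurrence hazards that
## increase with the 2020 known-mode risk class. Covariates are drawn
## independently within subgroup (only subgroup-conditional marginals are
## published); patient ids carry a SYN- prefix to mark them synthetic.

## exon of each whitelist hotspot (polymerase epsilon exonuclease domain)
.pole_hotspot_exon <- c(P286R = 9, M295R = 9, S297F = 9, F367S = 10,
                        D368Y = 10, V411L = 11, L424I = 11, P436R = 12,
                        M444K = 12, A456P = 13, S459F = 13)

#' Synthetic-cohort specification
#'
#' Bundles every parameter of the generator. Defaults reproduce the
#' development cohort's published structure: subgroup prevalences
#' 7.6/32.2/20.9/39.3%, per-subgroup histotype/grade/depth/LVSI/node/stage
#' distributions, multiple-classifier rates 1, 4, 9 and 2 per 211, residual
#' disease calibrated so about 7/211 land in the advanced/metastatic class,
#' and monthly exponential recurrence hazards increasing across the five 2020
#' known-mode risk classes (calibrated to roughly 13% recurrence at a median
#' follow-up near 22 months).
#'
#' @param n Cohort size (default 211).
#' @param subgroup_probs Named 4-vector over [molecular_subgroups()], sums
#'   to 1.
#' @param multiple_classifier_rates Cohort-level rates for the marker
#'   combinations `pole_mmrd`, `pole_p53abn`, `mmrd_p53abn`, `triple`.
#' @param histotype_by_subgroup,grade_by_subgroup,stage_by_subgroup,nodes_by_subgroup
#'   Per-subgroup categorical probability tables (columns = subgroups); the
#'   defaults are the published conditional frequencies. Stage rows are
#'   `IA`, `IB`, `II`, `III`, `IVA` (the published coarse IB/II and IV rows
#'   are split 32:10 and resolved to IVA respectively).
#' @param depth_ge50_by_subgroup,lvsi_positive_by_subgroup Per-subgroup
#'   probabilities of deep invasion and of any LVSI.
#' @param p_no_invasion_given_lt50 Fraction of <50% invasion tumors with no
#'   myometrial invasion at all (not published; 0.2 is a realistic share of
#'   endometrium-confined disease).
#' @param focal_fraction_of_lvsi_positive Split of LVSI-positive tumors into
#'   focal vs substantial (default the cohort-wide 66:75 ratio).
#' @param residual_prob_advanced_stage Probability that a stage III/IVA tumor
#'   has residual disease after surgery (default 7/50).
#' @param age_mean,age_sd,bmi_mean,bmi_sd Per-subgroup normal moments.
#' @param hazard_per_risk_class Monthly exponential recurrence hazards, one
#'   per risk class, strictly increasing.
#' @param censor_rate Monthly exponential censoring hazard (default
#'   log(2)/22, i.e. median administrative follow-up 22 months).
#' @param follow_up_cap Maximum follow-up in months (default 120).
#' @param seed Default seed used by [generate_cohort()].
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 211,
                        subgroup_probs = c(POLE = 16, MMRd = 68,
                                           p53abn = 44, NSMP = 83) / 211,
                        multiple_classifier_rates = c(pole_mmrd = 1,
                                                      pole_p53abn = 4,
                                                      mmrd_p53abn = 9,
                                                      triple = 2) / 211,
                        histotype_by_subgroup = NULL,
                        grade_by_subgroup = NULL,
                        stage_by_subgroup = NULL,
                        nodes_by_subgroup = NULL,
                        depth_ge50_by_subgroup = NULL,
                        lvsi_positive_by_subgroup = NULL,
                        p_no_invasion_given_lt50 = 0.2,
                        focal_fraction_of_lvsi_positive = 66 / 141,
                        residual_prob_advanced_stage = 7 / 50,
                        age_mean = c(58.6, 63.0, 66.9, 60.2),
                        age_sd = c(11.6, 9.4, 10.3, 10.2),
                        bmi_mean = c(27.2, 28.0, 25.5, 30.3),
                        bmi_sd = c(9.3, 7.3, 4.4, 8.1),
                        hazard_per_risk_class = c(
                          low = 0.001, intermediate = 0.003,
                          high_intermediate = 0.006, high = 0.009,
                          advanced_metastatic = 0.030),
                        censor_rate = log(2) / 22,
                        follow_up_cap = 120,
                        seed = 1L) {
  ref <- reference_cohort_tables()
  norm_cols <- function(m) sweep(m, 2, colSums(m), "/")
  if (is.null(histotype_by_subgroup))
    histotype_by_subgroup <- norm_cols(ref$histotype_by_subgroup)
  if (is.null(grade_by_subgroup))
    grade_by_subgroup <- norm_cols(ref$grade_by_subgroup)
  if (is.null(stage_by_subgroup)) {
    s <- ref$stage_by_subgroup
    ## split the coarse IB/II row 32:10 and resolve IV to IVA
    stage_by_subgroup <- rbind(IA = s["IA", ],
                               IB = s["IB_II", ] * 32 / 42,
                               II = s["IB_II", ] * 10 / 42,
                               III = s["III", ],
                               IVA = s["IV", ])
    stage_by_subgroup <- norm_cols(stage_by_subgroup)
  }
  if (is.null(nodes_by_subgroup)) {
    nb <- ref$nodes_by_subgroup
    unknown <- ref$subgroup_counts - colSums(nb)
    nodes_by_subgroup <- norm_cols(rbind(nb, unknown = unknown))
  }
  if (is.null(depth_ge50_by_subgroup))
    depth_ge50_by_subgroup <- ref$depth_ge50_by_subgroup / ref$subgroup_counts
  if (is.null(lvsi_positive_by_subgroup))
    lvsi_positive_by_subgroup <-
      ref$lvsi_positive_by_subgroup / ref$subgroup_counts

  ## vectors are positional (subgroups in molecular_subgroups() order, rates
  ## as pole_mmrd/pole_p53abn/mmrd_p53abn/triple); enforce canonical names
  if (length(subgroup_probs) == 4)
    names(subgroup_probs) <- molecular_subgroups()
  if (length(multiple_classifier_rates) == 4)
    names(multiple_classifier_rates) <- c("pole_mmrd", "pole_p53abn",
                                          "mmrd_p53abn", "triple")
  spec <- list(n = as.integer(n), subgroup_probs = subgroup_probs,
               multiple_classifier_rates = multiple_classifier_rates,
               histotype_by_subgroup = histotype_by_subgroup,
               grade_by_subgroup = grade_by_subgroup,
               stage_by_subgroup = stage_by_subgroup,
               nodes_by_subgroup = nodes_by_subgroup,
               depth_ge50_by_subgroup = depth_ge50_by_subgroup,
               lvsi_positive_by_subgroup = lvsi_positive_by_subgroup,
               p_no_invasion_given_lt50 = p_no_invasion_given_lt50,
               focal_fraction_of_lvsi_positive =
                 focal_fraction_of_lvsi_positive,
               residual_prob_advanced_stage = residual_prob_advanced_stage,
               age_mean = age_mean, age_sd = age_sd,
               bmi_mean = bmi_mean, bmi_sd = bmi_sd,
               hazard_per_risk_class = hazard_per_risk_class,
               censor_rate = censor_rate,
               follow_up_cap = follow_up_cap, seed = as.integer(seed))
  .validate_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

.validate_spec <- function(s) {
  bad <- character(0)
  tol <- 1e-9
  if (s$n < 1) bad <- c(bad, "n must be >= 1")
  if (length(s$subgroup_probs) != 4 ||
      abs(sum(s$subgroup_probs) - 1) > tol || any(s$subgroup_probs < 0))
    bad <- c(bad, "subgroup_probs must be a non-negative 4-vector summing to 1")
  for (nm in c("histotype_by_subgroup", "grade_by_subgroup",
               "stage_by_subgroup", "nodes_by_subgroup")) {
    m <- s[[nm]]
    if (any(m < 0) || any(abs(colSums(m) - 1) > tol))
      bad <- c(bad, paste0(nm, " columns must be probability vectors"))
  }
  for (nm in c("depth_ge50_by_subgroup", "lvsi_positive_by_subgroup",
               "p_no_invasion_given_lt50", "focal_fraction_of_lvsi_positive",
               "residual_prob_advanced_stage"))
    if (any(s[[nm]] < 0 | s[[nm]] > 1))
      bad <- c(bad, paste0(nm, " must lie in [0, 1]"))
  h <- s$hazard_per_risk_class
  if (length(h) != 5 || any(diff(h) <= 0) || any(h <= 0))
    bad <- c(bad, "hazard_per_risk_class must be 5 strictly increasing positive rates")
  r <- s$multiple_classifier_rates
  p <- s$subgroup_probs
  if (any(r < 0) ||
      r[["pole_mmrd"]] + r[["pole_p53abn"]] + r[["triple"]] > p[["POLE"]] + tol ||
      r[["mmrd_p53abn"]] > p[["MMRd"]] + tol)
    bad <- c(bad, "multiple_classifier_rates exceed the subgroup masses")
  if (s$censor_rate <= 0 || s$follow_up_cap <= 0)
    bad <- c(bad, "censor_rate and follow_up_cap must be positive")
  if (length(bad) > 0)
    stop("invalid cohort_spec:\n  - ", paste(bad, collapse = "\n  - "))
  invisible(s)
}

.sample_cat <- function(n, levels, prob) {
  if (length(levels) == 1) return(rep(levels, n))
  levels[sample.int(length(levels), n, replace = TRUE, prob = prob)]
}

#' Generate a synthetic endometrial carcinoma cohort
#'
#' Draws a fully specified cohort (clinicopathologic profile, marker panel,
#' POLE variant calls, disease-free survival) from a [cohort_spec()].
#' Marker panels are generated to re-classify exactly to the drawn subgroup
#' under the diagnostic hierarchy, including the injected multiple-classifier
#' cases; survival times are exponential with the hazard of the patient's
#' 2020 known-mode risk class, censored at the minimum of an exponential
#' censoring draw and the follow-up cap.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (default `spec$seed`); the same seed reproduces
#'   the cohort exactly.
#' @return List of class `ec_simulation`: `cohort` (an `ec_cohort` data
#'   frame), `variants` (POLE variant calls for the POLE-mutant patients),
#'   `truth` (drawn subgroup and classifier profile per patient), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  .validate_spec(spec)
  set.seed(seed)
  n <- spec$n
  sub_levels <- molecular_subgroups()
  subgroup <- .sample_cat(n, sub_levels, spec$subgroup_probs)

  ## classifier profile conditional on final subgroup (hierarchy-consistent)
  r <- spec$multiple_classifier_rates
  p <- spec$subgroup_probs
  profile <- character(n)
  i_pole <- which(subgroup == "POLE")
  if (length(i_pole) > 0) {
    cp <- c(r[["pole_mmrd"]], r[["pole_p53abn"]], r[["triple"]]) / p[["POLE"]]
    profile[i_pole] <- .sample_cat(length(i_pole),
                                   c("POLE,MMRd", "POLE,p53abn",
                                     "POLE,MMRd,p53abn", "POLE"),
                                   c(cp, 1 - sum(cp)))
  }
  i_mmrd <- which(subgroup == "MMRd")
  if (length(i_mmrd) > 0) {
    q <- r[["mmrd_p53abn"]] / p[["MMRd"]]
    profile[i_mmrd] <- .sample_cat(length(i_mmrd),
                                   c("MMRd,p53abn", "MMRd"), c(q, 1 - q))
  }
  profile[subgroup == "p53abn"] <- "p53abn"
  profile[subgroup == "NSMP"] <- ""

  has <- function(tag) vapply(strsplit(profile, ","), function(x) tag %in% x,
                              logical(1))
  pos_pole <- has("POLE")
  pos_mmr <- has("MMRd")
  pos_p53 <- has("p53abn")

  ## marker panels consistent with the profile
  p53_ihc <- rep("wildtype", n)
  p53_ihc[pos_p53] <- .sample_cat(sum(pos_p53),
                                  c("overexpression", "null_pattern",
                                    "cytoplasmic"), c(0.6, 0.3, 0.1))
  mmr <- matrix("retained", n, 4,
                dimnames = list(NULL, c("mlh1", "pms2", "msh2", "msh6")))
  if (any(pos_mmr)) {
    pat <- .sample_cat(sum(pos_mmr),
                       c("mlh1_pms2", "pms2", "msh2_msh6", "msh6"),
                       c(0.60, 0.10, 0.15, 0.15))
    idx <- which(pos_mmr)
    mmr[idx[pat == "mlh1_pms2"], c("mlh1", "pms2")] <- "lost"
    mmr[idx[pat == "pms2"], "pms2"] <- "lost"
    mmr[idx[pat == "msh2_msh6"], c("msh2", "msh6")] <- "lost"
    mmr[idx[pat == "msh6"], "msh6"] <- "lost"
  }
  pole_status <- ifelse(pos_pole, "pathogenic", "wildtype")

  ## POLE variant calls (always passing the default analytic filter)
  variants <- NULL
  if (any(pos_pole)) {
    k <- sum(pos_pole)
    hot <- names(.pole_hotspot_exon)
    w <- stats::setNames(rep(0.35 / 9, 11), hot)
    w[c("P286R", "V411L")] <- c(0.35, 0.30)   # the two dominant hotspots
    pc <- .sample_cat(k, hot, w)
    depth <- sample(400:1500, k, replace = TRUE)
    vaf <- round(stats::runif(k, 0.10, 0.45), 3)
    alt <- pmax(2, round(depth * vaf))
    fwd <- pmin(pmax(1, stats::rbinom(k, alt, 0.5)), alt - 1)
    variants <- data.frame(
      patient_id = sprintf("SYN-%04d", which(pos_pole)),
      gene = "POLE",
      protein_change = paste0("p.", pc),
      exon = unname(.pole_hotspot_exon[pc]),
      vaf = vaf, reads_forward = fwd, reads_reverse = alt - fwd,
      stringsAsFactors = FALSE)
  }

  ## clinicopathologic covariates, independent within subgroup
  sub_i <- match(subgroup, sub_levels)
  draw_by_sub <- function(tab) {
    out <- character(n)
    for (j in seq_along(sub_levels)) {
      i <- which(sub_i == j)
      if (length(i) > 0)
        out[i] <- .sample_cat(length(i), rownames(tab), tab[, j])
    }
    out
  }
  histotype <- draw_by_sub(spec$histotype_by_subgroup)
  grade <- draw_by_sub(spec$grade_by_subgroup)
  stage <- draw_by_sub(spec$stage_by_subgroup)
  nodes <- draw_by_sub(spec$nodes_by_subgroup)

  ## depth of invasion coherent with FIGO stage I definitions: IA is < 50%
  ## (none or inner half), IB is >= 50%; beyond stage I depth follows the
  ## per-subgroup deep-invasion probability
  deep <- stats::runif(n) < spec$depth_ge50_by_subgroup[sub_i]
  deep[stage == "IA"] <- FALSE
  deep[stage == "IB"] <- TRUE
  none <- !deep & stats::runif(n) < spec$p_no_invasion_given_lt50
  invasion <- ifelse(deep, "ge50", ifelse(none, "none", "lt50"))

  lvsi_pos <- stats::runif(n) < spec$lvsi_positive_by_subgroup[sub_i]
  focal <- stats::runif(n) < spec$focal_fraction_of_lvsi_positive
  lvsi <- ifelse(!lvsi_pos, "absent", ifelse(focal, "focal", "substantial"))

  residual <- stage %in% c("III", "IVA") &
    stats::runif(n) < spec$residual_prob_advanced_stage

  age <- round(pmin(pmax(stats::rnorm(n, spec$age_mean[sub_i],
                                      spec$age_sd[sub_i]), 30), 95), 1)
  bmi <- round(pmin(pmax(stats::rnorm(n, spec$bmi_mean[sub_i],
                                      spec$bmi_sd[sub_i]), 16), 60), 1)

  cohort <- data.frame(
    patient_id = sprintf("SYN-%04d", seq_len(n)),
    age_years = age, bmi = bmi, histotype = histotype, grade = grade,
    myometrial_invasion = invasion, lvsi = lvsi, lymph_nodes = nodes,
    figo_stage = stage, residual_disease = residual,
    p53_ihc = p53_ihc,
    mlh1 = mmr[, "mlh1"], pms2 = mmr[, "pms2"],
    msh2 = mmr[, "msh2"], msh6 = mmr[, "msh6"],
    pole_status = pole_status,
    dfs_months = NA_real_, recurrence_event = NA,
    stringsAsFactors = FALSE)

  ## survival from the 2020 known-mode risk class
  mol <- classify_molecular(cohort)
  risk <- classify_esgo2020(cohort, mol)$risk_class
  hazard <- spec$hazard_per_risk_class[risk]
  t_event <- stats::rexp(n, hazard)
  t_cens <- pmin(stats::rexp(n, spec$censor_rate), spec$follow_up_cap)
  cohort$recurrence_event <- t_event <= t_cens
  cohort$dfs_months <- pmax(round(pmin(t_event, t_cens), 2), 0.01)
  class(cohort) <- c("ec_cohort", "data.frame")

  structure(list(cohort = cohort, variants = variants,
                 truth = data.frame(patient_id = cohort$patient_id,
                                    subgroup = subgroup,
                                    classifier_profile = profile,
                                    risk_class_2020_known = risk,
                                    stringsAsFactors = FALSE),
                 spec = spec),
            class = "ec_simulation")
}

#' @export
print.ec_simulation <- function(x, ...) {
  cat("Synthetic endometrial carcinoma cohort: n =", nrow(x$cohort),
      "(seed", x$spec$seed, ")\n")
  print(round(prop.table(table(factor(x$truth$subgroup,
                                      molecular_subgroups()))), 3))
  invisible(x)
}
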