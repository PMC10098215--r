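## Prognostic risk stratification rule engines.
##
## Each system is an ordered list of rules evaluated on vectorized cohort
## columns; precedence runs advanced -> high -> high_intermediate ->
## intermediate -> low and the first matching rule fires, which makes overlap
## resolution explicit. Rule ids are stable and mirrored (with prose
## conditions and a version) in inst/rules/risk_rules.yaml.
##
## LVSI semantics differ between systems: the 2016 recommendations binarize
## lymphovascular space invasion (focal or substantial = positive), while the
## 2020 guidelines count only substantial LVSI against the patient.

.rule <- function(id, class, when) list(id = id, class = class, when = when)

## d is a data.frame with the cohort columns; each `when` returns a logical
## vector over rows. sub is the molecular subgroup vector (known mode only).

.rules_esmo2016 <- function(d) {
  endo <- d$histotype == "endometrioid"
  s1 <- d$figo_stage %in% .stage_i
  hg <- d$grade == "high"
  deep <- d$myometrial_invasion == "ge50"
  lvsi_pos <- d$lvsi %in% c("focal", "substantial")
  list(
    .rule("esmo2016/advanced", "advanced_metastatic",
          (d$figo_stage == "III" & d$residual_disease) |
            d$figo_stage %in% c("IVA", "IVB")),
    .rule("esmo2016/high_stage_iii", "high", d$figo_stage == "III"),
    .rule("esmo2016/high_nonendometrioid", "high", !endo),
    .rule("esmo2016/high_stage_ii", "high", d$figo_stage == "II"),
    .rule("esmo2016/high_g3_deep", "high", s1 & hg & deep),
    .rule("esmo2016/hi_int_g3_superficial", "high_intermediate",
          s1 & hg & !deep),
    .rule("esmo2016/hi_int_lvsi_positive", "high_intermediate",
          s1 & !hg & lvsi_pos),
    .rule("esmo2016/intermediate_deep", "intermediate", s1 & !hg & deep),
    .rule("esmo2016/low", "low", s1 & !hg & !deep)
  )
}

.rules_esgo2020 <- function(d, sub = NULL) {
  endo <- d$histotype == "endometrioid"
  hg <- d$grade == "high"
  inv <- d$myometrial_invasion != "none"
  subst <- d$lvsi == "substantial"
  s1 <- d$figo_stage %in% .stage_i
  early <- d$figo_stage %in% c(.stage_i, "II")   # stage I-II

  rules <- list(
    .rule("esgo2020/advanced", "advanced_metastatic",
          (d$figo_stage %in% c("III", "IVA") & d$residual_disease) |
            d$figo_stage == "IVB"),
    .rule("esgo2020/high_stage_iii_iva", "high",
          d$figo_stage %in% c("III", "IVA"))
  )
  if (!is.null(sub)) {
    ## Molecular overrides, confined to stage I-II: a pathogenic POLE mutation
    ## down-stages to low (including high-grade and stage II tumors); p53abn
    ## with myometrial invasion up-stages to high, without invasion at stage
    ## IA it is intermediate. Stage III/IV keeps its clinicopathologic class
    ## regardless of subgroup.
    rules <- c(rules, list(
      .rule("esgo2020k/low_pole_early", "low", early & sub == "POLE"),
      .rule("esgo2020k/high_p53abn_invasive", "high",
            early & sub == "p53abn" & (inv | d$figo_stage != "IA")),
      .rule("esgo2020k/int_p53abn_ia_noninvasive", "intermediate",
            d$figo_stage == "IA" & sub == "p53abn" & !inv)
    ))
  }
  c(rules, list(
    .rule("esgo2020/high_nonendo_invasive", "high",
          early & !endo & (inv | d$figo_stage == "IB")),
    .rule("esgo2020/hi_int_substantial_lvsi", "high_intermediate",
          s1 & endo & subst),
    .rule("esgo2020/hi_int_ib_high_grade", "high_intermediate",
          d$figo_stage == "IB" & endo & hg),
    .rule("esgo2020/hi_int_stage_ii", "high_intermediate",
          d$figo_stage == "II"),
    .rule("esgo2020/int_ib_low_grade", "intermediate",
          d$figo_stage == "IB" & endo & !hg),
    .rule("esgo2020/int_ia_high_grade", "intermediate",
          d$figo_stage == "IA" & endo & hg),
    .rule("esgo2020/int_ia_nonendo_noninvasive", "intermediate",
          d$figo_stage == "IA" & !endo & !inv),
    .rule("esgo2020/low", "low", d$figo_stage == "IA" & endo & !hg)
  ))
}

.fire_rules <- function(rules, n) {
  class_out <- rep(NA_character_, n)
  rule_out <- rep(NA_character_, n)
  for (r in rules) {
    hit <- r$when & is.na(class_out)
    hit[is.na(hit)] <- FALSE
    class_out[hit] <- r$class
    rule_out[hit] <- r$id
  }
  if (anyNA(class_out))
    stop("risk rule system has a gap: unclassified profile at row ",
         which(is.na(class_out))[1])
  data.frame(risk_class = class_out, fired_rule = rule_out,
             stringsAsFactors = FALSE)
}

.check_profiles <- function(d) {
  need <- c("histotype", "grade", "myometrial_invasion", "lvsi", "figo_stage")
  for (f in need) {
    v <- d[[f]]
    if (anyNA(v) || !all(v %in% .vocab[[f]]))
      stop("cannot stratify: field '", f, "' missing or illegal at row ",
           which(is.na(v) | !(v %in% .vocab[[f]]))[1])
  }
  if (anyNA(d$residual_disease))
    stop("cannot stratify: residual_disease missing")
  invisible(d)
}

#' Risk class under the ESMO 2016 recommendations
#'
#' Clinicopathologic-only five-class stratification. LVSI is binarized:
#' focal or substantial counts as positive.
#'
#' @param cohort Cohort data frame (or any data frame with `histotype`,
#'   `grade`, `myometrial_invasion`, `lvsi`, `figo_stage`,
#'   `residual_disease`).
#' @return Data frame with `patient_id`, `system`, `mode`, `risk_class`,
#'   `fired_rule`.
#' @export
classify_esmo2016 <- function(cohort) {
  d <- as.data.frame(cohort)
  .check_profiles(d)
  out <- .fire_rules(.rules_esmo2016(d), nrow(d))
  cbind(data.frame(patient_id = as.character(d$patient_id),
                   system = rep("esmo2016", nrow(d)),
                   mode = rep("unknown", nrow(d)),
                   stringsAsFactors = FALSE), out)
}

#' Risk class under the ESGO/ESTRO/ESP 2020 guidelines
#'
#' Five-class stratification with three-tier LVSI (only substantial LVSI is
#' adverse). With `molecular = NULL` the classification uses clinicopathologic
#' parameters alone ("molecular classification unknown"). With a molecular
#' call table the subgroup overrides apply at stage I-II: POLE-mutant tumors
#' are low risk, p53abn tumors with myometrial invasion are high risk (stage
#' IA without invasion: intermediate); MMRd and NSMP follow the
#' clinicopathologic rules, and stage III/IV is high or advanced regardless of
#' subgroup.
#'
#' @param cohort Cohort data frame.
#' @param molecular Optional [classify_molecular()] output (or any data frame
#'   with `patient_id` and `subgroup`) switching the engine to known mode.
#' @return Data frame with `patient_id`, `system`, `mode`, `risk_class`,
#'   `fired_rule`.
#' @export
classify_esgo2020 <- function(cohort, molecular = NULL) {
  d <- as.data.frame(cohort)
  .check_profiles(d)
  if (is.null(molecular)) {
    out <- .fire_rules(.rules_esgo2020(d), nrow(d))
    mode <- "unknown"
  } else {
    sub <- molecular$subgroup[match(as.character(d$patient_id),
                                    as.character(molecular$patient_id))]
    if (anyNA(sub) || !all(sub %in% .vocab$subgroup))
      stop("known-mode classification requires a complete molecular call ",
           "for every patient (missing/illegal subgroup at row ",
           which(is.na(sub) | !(sub %in% .vocab$subgroup))[1], ")")
    out <- .fire_rules(.rules_esgo2020(d, sub), nrow(d))
    mode <- "known"
  }
  cbind(data.frame(patient_id = as.character(d$patient_id),
                   system = rep("esgo2020", nrow(d)),
                   mode = rep(mode, nrow(d)),
                   stringsAsFactors = FALSE), out)
}

#' Stratify a cohort under one or more risk systems
#'
#' Convenience driver producing one assignment per patient per requested
#' system. Patients that cannot be classified in a requested mode (for
#' example, known mode with POLE never tested) are reported, not silently
#' dropped: they appear in the `errors` attribute and are omitted from the
#' assignment table.
#'
#' @param cohort Cohort data frame.
#' @param systems Subset of `c("esmo2016", "esgo2020_unknown",
#'   "esgo2020_known")`.
#' @param molecular Molecular call table; if `NULL` and known mode is
#'   requested, it is derived with [classify_molecular()] (which may fail per
#'   patient).
#' @param ruleset [pole_ruleset()] forwarded to [classify_molecular()].
#' @param variants Optional variants table forwarded to
#'   [classify_molecular()].
#' @return Long data frame of assignments with attribute `errors` (data frame
#'   `patient_id`, `system`, `reason`).
#' @export
classify_cohort <- function(cohort,
                            systems = c("esmo2016", "esgo2020_unknown",
                                        "esgo2020_known"),
                            molecular = NULL, variants = NULL,
                            ruleset = pole_ruleset()) {
  systems <- match.arg(systems, .vocab$system, several.ok = TRUE)
  d <- as.data.frame(cohort)
  res <- list()
  errs <- list()
  if ("esmo2016" %in% systems) res$a <- classify_esmo2016(d)
  if ("esgo2020_unknown" %in% systems) res$b <- classify_esgo2020(d)
  if ("esgo2020_known" %in% systems) {
    if (is.null(molecular)) {
      molecular <- tryCatch(classify_molecular(d, variants, ruleset),
                            error = function(e) NULL)
      if (is.null(molecular)) {
        ## classify row by row so only genuinely unresolvable patients drop out
        ok <- logical(nrow(d))
        calls <- vector("list", nrow(d))
        for (i in seq_len(nrow(d))) {
          calls[[i]] <- tryCatch(
            classify_molecular(d[i, , drop = FALSE], variants, ruleset),
            error = function(e) {
              errs[[length(errs) + 1]] <<- data.frame(
                patient_id = as.character(d$patient_id[i]),
                system = "esgo2020_known", reason = conditionMessage(e),
                stringsAsFactors = FALSE)
              NULL
            })
          ok[i] <- !is.null(calls[[i]])
        }
        molecular <- do.call(rbind, calls[ok])
        d_known <- d[ok, , drop = FALSE]
        if (!is.null(molecular) && nrow(d_known) > 0)
          res$c <- classify_esgo2020(d_known, molecular)
      } else {
        res$c <- classify_esgo2020(d, molecular)
      }
    } else {
      res$c <- classify_esgo2020(d, molecular)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  err_df <- if (length(errs) > 0) do.call(rbind, errs) else
    data.frame(patient_id = character(0), system = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  attr(out, "errors") <- err_df
  out
}

#' Risk rule-table metadata
#'
#' Returns the versioned rule table shipped with the package
#' (`inst/rules/risk_rules.yaml`): rule ids in precedence order with prose
#' conditions, for inspection and audit of `fired_rule` values.
#'
#' @return Named list with `version` and per-system rule listings.
#' @export
risk_rule_table <- function() {
  yaml::read_yaml(system.file("rules", "risk_rules.yaml",
                              package = "endorisk"))
}
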