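#' Validate one patient record
#'
#' Checks a single patient's clinicopathologic profile and marker panel against
#' the controlled vocabularies and cross-field invariants. Violations are
#' returned, not raised, so a whole cohort can be audited in one pass.
#'
#' Invariants checked beyond enum membership:
#' * `residual_disease` may be `TRUE` only for stage III/IVA/IVB;
#' * `age_years`, `bmi` positive when present; `dfs_months` non-negative;
#' * `recurrence_event` requires a `dfs_months` value.
#'
#' @param patient A named list or one-row data frame with (a subset of) the
#'   columns of [cohort_columns()].
#' @return Character vector of violation descriptors, each `"field: reason"`;
#'   empty if the record is valid.
#' @examples
#' validate_patient(list(patient_id = "P1", histotype = "endometrioid",
#'                       grade = "low", figo_stage = "IA",
#'                       myometrial_invasion = "lt50", lvsi = "absent"))
#' @export
validate_patient <- function(patient) {
  p <- as.list(patient)
  bad <- character(0)
  chk_enum <- function(field, legal) {
    v <- p[[field]]
    if (!is.null(v) && !is.na(v) && !(v %in% legal))
      bad <<- c(bad, sprintf("%s: illegal value '%s' (expected one of %s)",
                             field, v, paste(legal, collapse = "/")))
  }
  chk_enum("histotype", .vocab$histotype)
  chk_enum("grade", .vocab$grade)
  chk_enum("myometrial_invasion", .vocab$myometrial_invasion)
  chk_enum("lvsi", .vocab$lvsi)
  chk_enum("lymph_nodes", .vocab$lymph_nodes)
  chk_enum("figo_stage", .vocab$figo_stage)
  chk_enum("p53_ihc", .vocab$p53_ihc)
  for (m in c("mlh1", "pms2", "msh2", "msh6")) chk_enum(m, .vocab$mmr_ihc)
  chk_enum("pole_status", .vocab$pole_status)

  num_ok <- function(field, min, strict = FALSE) {
    v <- p[[field]]
    if (is.null(v) || is.na(v)) return(invisible())
    if (!is.numeric(v) || (strict && v <= min) || (!strict && v < min))
      bad <<- c(bad, sprintf("%s: must be a number %s %s", field,
                             if (strict) ">" else ">=", min))
  }
  num_ok("age_years", 0, strict = TRUE)
  num_ok("bmi", 0, strict = TRUE)
  num_ok("dfs_months", 0)

  rd <- p$residual_disease
  if (!is.null(rd) && !is.na(rd) && isTRUE(as.logical(rd)) &&
      !is.null(p$figo_stage) && !is.na(p$figo_stage) &&
      !(p$figo_stage %in% .stage_advanced))
    bad <- c(bad, sprintf(
      "residual_disease: TRUE is only allowed for stage III/IVA/IVB (stage is %s)",
      p$figo_stage))

  ev <- p$recurrence_event
  if (!is.null(ev) && !is.na(ev) && isTRUE(as.logical(ev)) &&
      (is.null(p$dfs_months) || is.na(p$dfs_months)))
    bad <- c(bad, "recurrence_event: event recorded without dfs_months")

  bad
}

#' Validate a cohort table
#'
#' Runs [validate_patient()] on every row.
#'
#' @param cohort A cohort data frame (see [cohort_columns()]).
#' @return Data frame with columns `row`, `patient_id`, `violation`; zero rows
#'   if the cohort is clean.
#' @export
validate_cohort <- function(cohort) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    v <- validate_patient(cohort[i, , drop = FALSE])
    if (length(v) == 0) return(NULL)
    data.frame(row = i, patient_id = as.character(cohort$patient_id[i]),
               violation = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(row = integer(0), patient_id = character(0),
                      violation = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
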