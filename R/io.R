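## Cohort CSV and variant-table input/output.
##
## Dialect: comma-separated, UTF-8, header required, "NA" or an empty cell is
## missing. Missing categorical cells map to explicit sentinels (lymph nodes
## "unknown", IHC "not_done", POLE "not_tested"); nothing is imputed.

.norm_grade <- function(x) {
  map <- c(low = "low", high = "high",
           G1 = "low", G2 = "low", G3 = "high",
           g1 = "low", g2 = "low", g3 = "high",
           "1" = "low", "2" = "low", "3" = "high")
  out <- unname(map[as.character(x)])
  out[is.na(x) | x == ""] <- NA_character_
  bad <- !is.na(x) & x != "" & is.na(out)
  out[bad] <- as.character(x)[bad]   # left illegal so validation names it
  out
}

## Coarse stage aliases: "IV" resolves to IVA unless residual/distant disease
## is flagged, in which case IVB; "III" is already a legal level.
.norm_stage <- function(x, residual) {
  x <- as.character(x)
  iv <- !is.na(x) & x == "IV"
  x[iv & residual %in% TRUE] <- "IVB"
  x[iv & !(residual %in% TRUE)] <- "IVA"
  x
}

.norm_logical <- function(x) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[s %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

.fill_missing <- function(x, sentinel) {
  x <- as.character(x)
  x[is.na(x) | trimws(x) == ""] <- sentinel
  x
}

#' Read a cohort CSV
#'
#' Parses the per-patient cohort table, checks the header against
#' [cohort_columns()], normalizes convenience aliases (FIGO grade G1/G2 to
#' `low`, G3 to `high`; coarse stage `IV` to `IVA`, or `IVB` when
#' `residual_disease` is set) and maps missing cells to explicit sentinels.
#'
#' @param path Path to a CSV file with the [cohort_columns()] header.
#' @param validate If `TRUE` (default), stop with a summary when any row
#'   violates the schema; set `FALSE` to load anyway and inspect with
#'   [validate_cohort()].
#' @return A data frame of class `ec_cohort`, one row per patient.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = c("NA", ""), check.names = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(raw))
  if (length(missing_cols) > 0)
    stop("malformed cohort header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[, cohort_columns()]

  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad) > 0)
      stop(sprintf("unparseable numeric cell: row %d, column %s ('%s')",
                   bad[1], col, raw[[col]][bad[1]]))
    v
  }
  residual <- .norm_logical(raw$residual_disease)
  residual[is.na(residual)] <- FALSE

  cohort <- data.frame(
    patient_id = as.character(raw$patient_id),
    age_years = num("age_years"),
    bmi = num("bmi"),
    histotype = as.character(raw$histotype),
    grade = .norm_grade(raw$grade),
    myometrial_invasion = as.character(raw$myometrial_invasion),
    lvsi = as.character(raw$lvsi),
    lymph_nodes = .fill_missing(raw$lymph_nodes, "unknown"),
    figo_stage = .norm_stage(raw$figo_stage, residual),
    residual_disease = residual,
    p53_ihc = .fill_missing(raw$p53_ihc, "not_done"),
    mlh1 = .fill_missing(raw$mlh1, "not_done"),
    pms2 = .fill_missing(raw$pms2, "not_done"),
    msh2 = .fill_missing(raw$msh2, "not_done"),
    msh6 = .fill_missing(raw$msh6, "not_done"),
    pole_status = .fill_missing(raw$pole_status, "not_tested"),
    dfs_months = num("dfs_months"),
    recurrence_event = .norm_logical(raw$recurrence_event),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(cohort$patient_id))
    stop("duplicate patient_id in cohort: ",
         cohort$patient_id[duplicated(cohort$patient_id)][1])
  if (validate) {
    bad <- validate_cohort(cohort)
    if (nrow(bad) > 0)
      stop("cohort fails validation (", nrow(bad), " violation(s)); first: row ",
           bad$row[1], " — ", bad$violation[1])
  }
  class(cohort) <- c("ec_cohort", "data.frame")
  cohort
}

#' Write a cohort CSV
#'
#' Serializes a cohort so that `read_cohort(write_cohort(x))` reproduces `x`
#' field for field. Missing values are written as empty cells.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns()]
  df$residual_disease <- ifelse(df$residual_disease %in% TRUE, "true", "false")
  df$recurrence_event <- ifelse(is.na(df$recurrence_event), NA,
                                ifelse(df$recurrence_event, "true", "false"))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a variants table (CSV)
#'
#' Per-patient variant calls used as an alternative to a precomputed
#' `pole_status` column. Expected columns: `patient_id`, `gene`,
#' `protein_change`, `exon`, `vaf`, `reads_forward`, `reads_reverse`.
#'
#' @param path CSV path.
#' @return Data frame of validated variant calls.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("variants file not found: ", path)
  need <- c("patient_id", "gene", "protein_change", "exon", "vaf",
            "reads_forward", "reads_reverse")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("malformed variants header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, need]
  .check_variants(df)
  df
}

.check_variants <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$vaf)) || any(df$vaf < 0 | df$vaf > 1))
    stop("variant vaf must lie in [0, 1]")
  for (col in c("reads_forward", "reads_reverse")) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v < 0) || any(v != floor(v)))
      stop(col, " must be non-negative integer counts")
  }
  invisible(df)
}

#' Read variant calls from a VCF
#'
#' Minimal VCF 4.2 reader for targeted-panel calls (requires the `vcfR`
#' package). Per-record INFO keys consumed: `GENE` (symbol), `PC` (HGVS p.
#' change), `EXON` (integer), `AF` (allele fraction), `SAF`/`SAR` (alt reads on
#' forward/reverse strand); the sample column name is taken as `patient_id`
#' unless INFO `PID` is present.
#'
#' @param path VCF path (plain text or bgzip).
#' @return Data frame in the [read_variants()] layout.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variants_vcf() requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  info <- function(key) vcfR::extract.info(v, element = key)
  pid <- info("PID")
  if (all(is.na(pid))) {
    samples <- colnames(v@gt)[-1]
    pid <- rep(if (length(samples) > 0) samples[1] else NA_character_, n)
  }
  df <- data.frame(
    patient_id = pid,
    gene = info("GENE"),
    protein_change = info("PC"),
    exon = suppressWarnings(as.integer(info("EXON"))),
    vaf = suppressWarnings(as.numeric(info("AF"))),
    reads_forward = suppressWarnings(as.integer(info("SAF"))),
    reads_reverse = suppressWarnings(as.integer(info("SAR"))),
    stringsAsFactors = FALSE
  )
  .check_variants(df)
  df
}
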