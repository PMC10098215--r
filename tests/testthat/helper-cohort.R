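# Shared builders for in-code fixtures; nothing is stored on disk.

# One patient row with sensible defaults, overridable field by field.
make_patient <- function(patient_id = "P1", ...) {
  row <- list(patient_id = patient_id, age_years = 62, bmi = 28,
              histotype = "endometrioid", grade = "low",
              myometrial_invasion = "lt50", lvsi = "absent",
              lymph_nodes = "negative", figo_stage = "IA",
              residual_disease = FALSE, p53_ihc = "wildtype",
              mlh1 = "retained", pms2 = "retained", msh2 = "retained",
              msh6 = "retained", pole_status = "wildtype",
              dfs_months = 24, recurrence_event = FALSE)
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  co <- do.call(rbind, rows)
  co$patient_id <- make.unique(co$patient_id)
  class(co) <- c("ec_cohort", "data.frame")
  co
}

# Exhaustive clinicopathologic grid (1296 profiles).
profile_grid <- function() {
  g <- expand.grid(histotype = cohort_vocabulary()$histotype,
                   grade = cohort_vocabulary()$grade,
                   figo_stage = cohort_vocabulary()$figo_stage,
                   myometrial_invasion = cohort_vocabulary()$myometrial_invasion,
                   lvsi = cohort_vocabulary()$lvsi,
                   residual_disease = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  g$patient_id <- sprintf("G%04d", seq_len(nrow(g)))
  g
}

# Marker columns realizing one of the 8 POLE x MMR x p53 combinations.
marker_cols <- function(pole, mmr, p53) {
  list(pole_status = if (pole) "pathogenic" else "wildtype",
       mlh1 = if (mmr) "lost" else "retained",
       pms2 = if (mmr) "lost" else "retained",
       msh2 = "retained", msh6 = "retained",
       p53_ihc = if (p53) "overexpression" else "wildtype")
}

# Small cohort CSV fixture written to a temp file.
write_fixture_csv <- function(path = tempfile(fileext = ".csv")) {
  lines <- c(
    paste(cohort_columns(), collapse = ","),
    "A1,61.5,27.1,endometrioid,G1,lt50,absent,negative,IA,false,wildtype,retained,retained,retained,retained,wildtype,30,false",
    "A2,70,31,serous,G3,ge50,substantial,positive,III,true,overexpression,retained,retained,retained,retained,wildtype,12,true",
    "A3,55,24,endometrioid,low,none,focal,,IV,false,wildtype,lost,lost,retained,retained,not_tested,,")
  writeLines(lines, path)
  path
}

# Minimal VCF 4.2 fixture with the INFO keys read_variants_vcf() consumes.
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=PID,Number=1,Type=String,Description=\"Patient id\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=PC,Number=1,Type=String,Description=\"Protein change\">",
    "##INFO=<ID=EXON,Number=1,Type=Integer,Description=\"Exon\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads forward\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads reverse\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "12\t133250250\t.\tG\tC\t.\tPASS\tPID=A3;GENE=POLE;PC=p.P286R;EXON=9;AF=0.32;SAF=150;SAR=140",
    "12\t133249000\t.\tC\tT\t.\tPASS\tPID=A3;GENE=POLE;PC=p.A100T;EXON=5;AF=0.40;SAF=90;SAR=85",
    "17\t7577538\t.\tC\tT\t.\tPASS\tPID=A3;GENE=TP53;PC=p.R248W;EXON=7;AF=0.03;SAF=10;SAR=9")
  writeLines(lines, path)
  path
}
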