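## Risk-class migration between stratification systems.

#' Cross-tabulate risk assignments from two systems
#'
#' Builds the 5x5 migration matrix, rows = risk class under the first system,
#' columns = class under the second, in the fixed order
#' [risk_classes()]. Both assignment tables must cover exactly the same
#' patients.
#'
#' @param row_assign,col_assign Assignment tables ([classify_esmo2016()] /
#'   [classify_esgo2020()] output, or any data frame with `patient_id` and
#'   `risk_class`).
#' @param row_label,col_label Labels for the two systems (default derived
#'   from the `system`/`mode` columns when present).
#' @return Object of class `migration_matrix`: a list with `counts` (5x5
#'   integer matrix), `n`, `row_system`, `col_system`.
#' @export
migration_matrix <- function(row_assign, col_assign,
                             row_label = NULL, col_label = NULL) {
  lab <- function(a, fallback) {
    if (!is.null(a$system))
      paste0(a$system[1], if (!is.null(a$mode)) paste0("_", a$mode[1]) else "")
    else fallback
  }
  row_label <- row_label %||% lab(row_assign, "rows")
  col_label <- col_label %||% lab(col_assign, "cols")
  rid <- as.character(row_assign$patient_id)
  cid <- as.character(col_assign$patient_id)
  if (length(rid) != length(cid) || !setequal(rid, cid) ||
      anyDuplicated(rid) || anyDuplicated(cid))
    stop("migration_matrix: the two systems must cover the same patients ",
         "exactly once each")
  cls <- risk_classes()
  rc <- factor(row_assign$risk_class, levels = cls)
  cc <- factor(col_assign$risk_class[match(rid, cid)], levels = cls)
  if (anyNA(rc) || anyNA(cc)) stop("illegal risk_class in assignments")
  counts <- table(rc, cc, dnn = NULL)
  structure(list(counts = unclass(as.matrix(counts)), n = length(rid),
                 row_system = row_label, col_system = col_label),
            class = "migration_matrix")
}

#' Build a migration matrix from printed counts
#'
#' Wraps a known 5x5 cross-tabulation (for example one transcribed from a
#' published report) as a `migration_matrix` so that [migration_summary()]
#' can be applied to it.
#'
#' @param counts 5x5 matrix of non-negative integers, rows and columns in
#'   [risk_classes()] order.
#' @param row_label,col_label System labels.
#' @return A `migration_matrix`.
#' @export
as_migration_matrix <- function(counts, row_label = "rows",
                                col_label = "cols") {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(5, 5)) || any(counts < 0) ||
      any(counts != floor(counts)))
    stop("counts must be a 5x5 matrix of non-negative integers")
  dimnames(counts) <- list(risk_classes(), risk_classes())
  structure(list(counts = counts, n = sum(counts),
                 row_system = row_label, col_system = col_label),
            class = "migration_matrix")
}

#' Summarize risk-class migration
#'
#' Off-diagonal mass of a migration matrix split by direction: "down" means
#' the column (second system) class is lower on the [risk_classes()] scale
#' than the row class, "up" the opposite.
#'
#' @param m A [migration_matrix()].
#' @return List of class `migration_summary`: `n`, `n_changed`,
#'   `frac_changed`, `n_down`, `n_up`, `frac_down`, `frac_up`.
#' @export
migration_summary <- function(m) {
  stopifnot(inherits(m, "migration_matrix"))
  cnt <- m$counts
  idx <- row(cnt) - col(cnt)
  n_down <- sum(cnt[idx > 0])   # column class below row class
  n_up <- sum(cnt[idx < 0])
  out <- list(n = m$n, n_changed = n_down + n_up,
              frac_changed = (n_down + n_up) / m$n,
              n_down = n_down, n_up = n_up,
              frac_down = n_down / m$n, frac_up = n_up / m$n,
              row_system = m$row_system, col_system = m$col_system)
  class(out) <- "migration_summary"
  out
}

#' @export
print.migration_matrix <- function(x, ...) {
  cat("Risk-class migration:", x$row_system, "(rows) vs", x$col_system,
      "(cols), n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' @export
print.migration_summary <- function(x, ...) {
  cat(sprintf(
    "%s -> %s: %d/%d changed (%.1f%%): %d down (%.1f%%), %d up (%.1f%%)\n",
    x$row_system, x$col_system, x$n_changed, x$n, 100 * x$frac_changed,
    x$n_down, 100 * x$frac_down, x$n_up, 100 * x$frac_up))
  invisible(x)
}
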