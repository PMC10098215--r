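#' POLE variant interpretation ruleset
#'
#' Bundles the parameters used to call a tumor POLE-mutant from targeted
#' sequencing of the polymerase epsilon exonuclease domain: a whitelist of
#' pathogenic hotspot protein changes, the exons covered by the panel, the
#' minimum variant allele fraction, and whether a call must be supported by
#' reads on both strands.
#'
#' @param whitelist Character vector of HGVS p. changes (without the `p.`
#'   prefix) accepted as pathogenic. The default holds the eleven canonical
#'   exonuclease-domain hotspots used for clinical POLE calls.
#' @param covered_exons Integer vector of exons covered (default 9:14).
#' @param vaf_min Minimum variant allele fraction in (0, 1); "at least 5%" is
#'   read inclusively as `vaf >= 0.05`.
#' @param require_both_strands Require alt reads on both strands (default
#'   `TRUE`).
#' @return A list of class `pole_ruleset`.
#' @seealso [filter_variants()], [interpret_pole()], [read_pole_ruleset()]
#' @export
pole_ruleset <- function(whitelist = c("P286R", "V411L", "S297F", "S459F",
                                       "F367S", "L424I", "M295R", "P436R",
                                       "M444K", "D368Y", "A456P"),
                         covered_exons = 9:14,
                         vaf_min = 0.05,
                         require_both_strands = TRUE) {
  whitelist <- toupper(sub("^p\\.", "", whitelist))
  if (length(whitelist) == 0) stop("pole_ruleset whitelist must be non-empty")
  if (!is.numeric(vaf_min) || vaf_min <= 0 || vaf_min >= 1)
    stop("vaf_min must lie in (0, 1)")
  structure(list(whitelist = whitelist,
                 covered_exons = as.integer(covered_exons),
                 vaf_min = vaf_min,
                 require_both_strands = isTRUE(require_both_strands)),
            class = "pole_ruleset")
}

#' Load a POLE ruleset from YAML
#'
#' Reads a `pole_ruleset:` block (keys `whitelist`, `covered_exons`,
#' `vaf_min`, `require_both_strands`); absent keys fall back to the package
#' defaults. The shipped default lives at
#' `system.file("rules", "pole_ruleset.yaml", package = "endorisk")`.
#'
#' @param path YAML file path.
#' @return A `pole_ruleset`.
#' @export
read_pole_ruleset <- function(path = system.file("rules", "pole_ruleset.yaml",
                                                 package = "endorisk")) {
  y <- yaml::read_yaml(path)
  y <- y$pole_ruleset %||% y
  d <- pole_ruleset()
  pole_ruleset(whitelist = unlist(y$whitelist) %||% d$whitelist,
               covered_exons = unlist(y$covered_exons) %||% d$covered_exons,
               vaf_min = y$vaf_min %||% d$vaf_min,
               require_both_strands = y$require_both_strands %||%
                 d$require_both_strands)
}

#' @export
print.pole_ruleset <- function(x, ...) {
  cat("POLE ruleset: exons", paste(range(x$covered_exons), collapse = "-"),
      "| VAF >=", x$vaf_min,
      "| both strands:", x$require_both_strands, "\n")
  cat("  whitelist:", paste(x$whitelist, collapse = ", "), "\n")
  invisible(x)
}
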