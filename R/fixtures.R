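#' Packaged reference tables from the Mecp2-null cortex study
#'
#' Machine-readable transcriptions of the published result tables of the
#' Rett-syndrome (Mecp2-deficient) mouse cortex metabolomics study this
#' pipeline re-implements: the per-mouse phenotype table (12 animals, 4
#' measurements), the 101 significantly deregulated identified
#' metabolites (log2 fold change, average expression, raw and adjusted
#' p-value), and the 41 tested KEGG metabolism pathways (feature and
#' contributor counts, direction, raw and adjusted p-value, category).
#' These serve as in-package reference data: the raw intensities behind
#' them are not public, so the published summary rows are the only
#' recomputable anchor.
#'
#' @return A data frame (`reference_phenotypes()`: one row per mouse;
#'   `reference_metabolites()`: one row per metabolite;
#'   `reference_pathways()`: one row per pathway).
#' @name reference_tables
NULL

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "metadereg")
  if (!nzchar(path)) stop("packaged table not found: ", name)
  path
}

#' @rdname reference_tables
#' @export
reference_phenotypes <- function() {
  df <- utils::read.delim(.extdata("mecp2_cortex_phenotypes.tsv"),
                          colClasses = c(sample_id = "character"))
  sample_info(df)
}

#' @rdname reference_tables
#' @export
reference_metabolites <- function() {
  utils::read.delim(.extdata("mecp2_cortex_metabolites.tsv"),
                    check.names = FALSE)
}

#' @rdname reference_tables
#' @export
reference_pathways <- function() {
  utils::read.delim(.extdata("mecp2_cortex_pathways.tsv"),
                    check.names = FALSE)
}
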