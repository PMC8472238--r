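#' Run the full deregulation pipeline
#'
#' End-to-end orchestration: read inputs (or accept in-memory objects),
#' preprocess (normalize, log, impute), per-metabolite moderated testing
#' with BH adjustment, pathway set construction, rotation-based pathway
#' testing, and the descriptive summaries. Writes result TSVs, the
#' preprocessing provenance and a reproducibility manifest into
#' `output_dir` when given.
#'
#' @param matrix A [feature_matrix()] or path to an intensity table.
#' @param info A [sample_info()] data frame or path to a sample TSV.
#' @param annotation An [annotation_table()] or path.
#' @param pathways A [pathway_db()] or GMT path.
#' @param output_dir Optional directory for result files.
#' @param alpha Metabolite significance threshold on adjusted p (strict
#'   `<`, default 0.05).
#' @param pathway_alpha Pathway significance threshold on adjusted p
#'   (`<=`, default 0.05).
#' @param log_base Log base for the transform (default 2).
#' @param pseudocount Offset added before the log (default 0).
#' @param B Number of rotations (default 9999).
#' @param seed Seed for the rotation draws (default 1).
#' @param min_set_size Minimum pathway set size (default 3).
#' @param restrict_to_identified Run the metabolite-level test (and its
#'   BH family) on uniquely identified features only (default `TRUE`,
#'   mirroring a targeted read-out of an untargeted screen); when
#'   `FALSE`, all features are tested.
#' @return A list classed `dereg_run` with elements `diff`, `pathway`,
#'   `pca`, `volcano`, `normalized`, `sets`, `prior` and `config`.
#' @export
run_pipeline <- function(matrix, info, annotation, pathways,
                         output_dir = NULL,
                         alpha = 0.05, pathway_alpha = 0.05,
                         log_base = 2, pseudocount = 0,
                         B = 9999L, seed = 1L, min_set_size = 3L,
                         restrict_to_identified = TRUE) {
  for (arg in list(matrix, info, annotation, pathways))
    if (is.character(arg) && !file.exists(arg))
      stop("input file not found: ", arg)
  if (is.character(matrix)) matrix <- read_feature_matrix(matrix)
  if (is.character(info))
    info <- sample_info(utils::read.delim(info,
                                          colClasses = c(sample_id = "character")))
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  if (is.character(pathways)) pathways <- read_gmt(pathways)
  stopifnot(alpha > 0, alpha < 1)

  norm <- preprocess(matrix, base = log_base, pseudocount = pseudocount)

  test_m <- norm
  if (restrict_to_identified) {
    keep <- intersect(rownames(norm$values),
                      annotation$feature_id[annotation$uniquely_identified])
    if (length(keep) < 10L)
      stop("fewer than 10 uniquely identified features to test")
    test_m <- feature_matrix(norm$values[keep, , drop = FALSE],
                             norm$platform[keep], log_scale = TRUE)
  }
  diff <- diff_test(test_m, info, annotation = annotation)
  prior <- attr(diff, "prior")

  sets <- build_pathway_sets(pathways, annotation, diff$feature_id,
                             min_size = min_set_size)
  frame <- make_rotation_frame(test_m, info)
  pw <- roast_test(frame, sets, prior,
                   rotation_config(B = B, seed = seed))

  pca <- pca_scores(norm)
  volc <- volcano_table(diff, alpha = alpha)

  run <- structure(
    list(diff = diff, pathway = pw, pca = pca, volcano = volc,
         normalized = norm, sets = sets, prior = prior,
         config = list(alpha = alpha, pathway_alpha = pathway_alpha,
                       log_base = log_base, pseudocount = pseudocount,
                       B = B, seed = seed, min_set_size = min_set_size,
                       m_tests = attr(diff, "m_tests"),
                       p_floor = 1 / (B + 1),
                       restrict_to_identified = restrict_to_identified)),
    class = "dereg_run")

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write_results(diff, pw, output_dir, full = TRUE)
    write_provenance(norm, output_dir)
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores),
                 round(pca$scores[, seq_len(min(5L, ncol(pca$scores))),
                                  drop = FALSE], 6)),
      file.path(output_dir, "pca_scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- c(
      sprintf("package_version: %s",
              as.character(utils::packageVersion("metadereg"))),
      sprintf("r_version: %s", R.version.string),
      sprintf("seed: %d", seed), sprintf("rotations: %d", B),
      sprintf("m_tests: %d", attr(diff, "m_tests")),
      sprintf("p_floor: %.3g", 1 / (B + 1)),
      sprintf("d0: %s", format(prior$d0, digits = 6)),
      sprintf("s0_2: %s", format(prior$s0_2, digits = 6)),
      sprintf("n_imputed: %d", norm$n_imputed),
      sprintf("pathways_discarded: %d", attr(sets, "n_discarded")))
    writeLines(manifest, file.path(output_dir, "manifest.txt"))
  }
  run
}

#' Summarize significance counts of a run or result tables
#'
#' Counts significantly deregulated metabolites (adjusted p strictly
#' below `alpha`), split by fold-change sign, and tested/significant
#' pathways (adjusted p at or below `pathway_alpha`), split by direction.
#'
#' @param run A `dereg_run` from [run_pipeline()], or a list with
#'   elements `diff` and `pathway` holding data frames with `adjP`,
#'   `logFC` / `direction` columns (e.g. the packaged reference tables).
#' @param alpha Metabolite threshold (strict `<`; default 0.05).
#' @param pathway_alpha Pathway threshold (`<=`; default 0.05).
#' @return A named list of counts: `n_metabolites`, `n_significant`,
#'   `n_up`, `n_down`, `n_pathways_tested`, `n_pathways_significant`,
#'   `n_pathways_up`, `n_pathways_down`.
#' @export
summarize_run <- function(run, alpha = 0.05, pathway_alpha = 0.05) {
  diff <- run$diff
  pw <- run$pathway
  if (is.null(diff) || is.null(pw))
    stop("run is incomplete: needs `diff` and `pathway` tables")
  sig <- !is.na(diff$adjP) & diff$adjP < alpha
  psig <- !is.na(pw$adjP) & pw$adjP <= pathway_alpha
  list(n_metabolites = nrow(diff),
       n_significant = sum(sig),
       n_up = sum(sig & diff$logFC > 0),
       n_down = sum(sig & diff$logFC < 0),
       n_pathways_tested = nrow(pw),
       n_pathways_significant = sum(psig),
       n_pathways_up = sum(psig & pw$direction == "Up"),
       n_pathways_down = sum(psig & pw$direction == "Down"))
}

#' @export
print.dereg_run <- function(x, ...) {
  s <- summarize_run(x, x$config$alpha, x$config$pathway_alpha)
  cat("dereg_run\n")
  cat(sprintf("  metabolites tested: %d (BH family m = %d)\n",
              s$n_metabolites, x$config$m_tests))
  cat(sprintf("  significant (adjP < %.3g): %d (%d up, %d down)\n",
              x$config$alpha, s$n_significant, s$n_up, s$n_down))
  cat(sprintf("  pathways tested: %d; significant (adjP <= %.3g): %d (%d Up, %d Down)\n",
              s$n_pathways_tested, x$config$pathway_alpha,
              s$n_pathways_significant, s$n_pathways_up, s$n_pathways_down))
  cat(sprintf("  rotations B = %d (p floor %.3g), seed %d\n",
              x$config$B, x$config$p_floor, x$config$seed))
  invisible(x)
}
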