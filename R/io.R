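#' Read a feature intensity table
#'
#' Expects the first column to hold feature ids, the second the platform
#' tag (`uplc_pos`, `uplc_neg` or `gcms`) and the remaining columns one
#' sample each. Empty cells or the `missing` sentinel denote absent
#' measurements.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param missing Sentinel string for missing values (default `"NA"`).
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path, dialect = c("tsv", "csv"),
                                missing = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 3L)
    stop("intensity table needs feature id, platform and >= 1 sample column")
  ids <- df[[1L]]
  platform <- df[[2L]]
  samp <- colnames(df)[-(1:2)]
  dup <- samp[duplicated(samp)]
  if (length(dup))
    stop("duplicate sample id: ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  vals[vals == missing | vals == ""] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad))
    stop("non-numeric intensity for feature: ",
         paste(unique(ids[row(vals)[bad]]), collapse = ", "))
  if (any(num < 0, na.rm = TRUE))
    stop("negative intensity for feature: ",
         paste(unique(ids[rowSums(num < 0, na.rm = TRUE) > 0]), collapse = ", "))
  dimnames(num) <- list(ids, samp)
  feature_matrix(num, platform)
}

#' Write a feature intensity table
#'
#' Inverse of [read_feature_matrix()]; round-trips values losslessly
#' (full double precision) including missing-value sentinels.
#'
#' @param m A [feature_matrix()].
#' @param path File path.
#' @inheritParams read_feature_matrix
#' @export
write_feature_matrix <- function(m, path, dialect = c("tsv", "csv"),
                                 missing = "NA") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  vals <- format(m$values, digits = 17, trim = TRUE, scientific = TRUE)
  vals[is.na(m$values)] <- missing
  df <- data.frame(feature_id = rownames(m$values),
                   platform = m$platform,
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature annotation table
#'
#' Two tab-separated columns: feature id, then the matched compound
#' name(s). Coeluting matches are joined by `sep` (default `";"`).
#'
#' @param path File path.
#' @param sep Separator between coeluting compound names.
#' @return An [annotation_table()].
#' @export
read_annotation <- function(path, sep = ";") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L)
    stop("annotation table needs feature id and compound columns")
  comp <- strsplit(df[[2L]], sep, fixed = TRUE)
  comp <- lapply(comp, function(x) trimws(x[nzchar(trimws(x))]))
  empty <- vapply(comp, length, integer(1)) == 0L
  if (any(empty))
    stop("empty compound field for feature: ",
         paste(df[[1L]][empty], collapse = ", "))
  annotation_table(df[[1L]], comp)
}

#' Write a feature annotation table
#' @param ann An [annotation_table()].
#' @param path File path.
#' @param sep Separator between coeluting compound names.
#' @export
write_annotation <- function(ann, path, sep = ";") {
  df <- data.frame(
    feature_id = ann$feature_id,
    compounds = vapply(ann$compounds, paste, character(1), collapse = sep),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway definitions in GMT format
#'
#' Standard tab-separated GMT: pathway name, description (used here as the
#' pathway category, e.g. a KEGG top-level class), then member compound
#' names. Duplicate members within a line are deduplicated.
#'
#' @param path File path.
#' @return A [pathway_db()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  cat_ <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  pathway_db(sets, cat_)
}

#' Write pathway definitions in GMT format
#' @param db A [pathway_db()].
#' @param path File path.
#' @export
write_gmt <- function(db, path) {
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, db$category[[nm]], db$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write differential and pathway result tables
#'
#' Emits two TSVs: `metabolites.tsv` (compound, log2 fold change, average
#' expression, raw and adjusted p-value, plus moderated-t columns when
#' `full = TRUE`) and `pathways.tsv` (pathway, feature counts, up/down
#' contributor counts, direction, raw and adjusted p-value, category).
#'
#' @param diff A `diff_result` data frame (see [diff_test()]); may be
#'   empty.
#' @param pathways A `pathway_result` data frame (see [roast_test()]);
#'   may be empty.
#' @param dir Output directory (created if needed).
#' @param digits Significant digits for numeric columns (default 6).
#' @param full Include moderated-t, df and z columns in the metabolite
#'   table.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(diff, pathways, dir, digits = 6, full = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(x) if (is.numeric(x)) signif(x, digits) else x
  dcols <- c("compound", "logFC", "aveExpr",
             if (full) c("t", "df_total", "z"), "p", "adjP")
  d <- as.data.frame(diff)[, intersect(dcols, names(diff)), drop = FALSE]
  d[] <- lapply(d, fmt)
  p1 <- file.path(dir, "metabolites.tsv")
  utils::write.table(d, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  pcols <- c("pathway", "n_features", "n_down", "n_up", "direction",
             "p", "adjP", "group")
  pw <- as.data.frame(pathways)[, intersect(pcols, names(pathways)), drop = FALSE]
  pw[] <- lapply(pw, fmt)
  p2 <- file.path(dir, "pathways.tsv")
  utils::write.table(pw, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(metabolites = p1, pathways = p2))
}
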