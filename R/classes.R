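#' Construct a feature-by-sample intensity matrix
#'
#' The raw input of the pipeline: one row per mass-spectrometric feature
#' (an LC retention-time/m-z pair or a GC mass trace), one column per sample,
#' with a per-feature acquisition-platform tag. Raw-scale intensities are
#' non-negative; absent measurements are `NA`.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row and column names are required and must be unique.
#' @param platform Character vector, one of `"uplc_pos"`, `"uplc_neg"`,
#'   `"gcms"` per feature. Recycled if length 1.
#' @param log_scale Logical; `FALSE` for raw intensities (the usual entry
#'   point), `TRUE` once values have been log-transformed.
#' @return An object of class `feature_matrix`: a list with elements
#'   `values`, `platform` (named by feature) and `log_scale`.
#' @examples
#' m <- matrix(c(10, 20, 30, 40), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' fm <- feature_matrix(m, platform = "gcms")
#' dim(fm)
#' @export
feature_matrix <- function(values, platform, log_scale = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature row names and sample column names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature id: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id: ", paste(unique(dup), collapse = ", "))
  if (length(platform) == 1L) platform <- rep(platform, nrow(values))
  if (length(platform) != nrow(values))
    stop("`platform` must have one tag per feature")
  bad <- setdiff(unique(platform), c("uplc_pos", "uplc_neg", "gcms"))
  if (length(bad))
    stop("unknown platform tag: ", paste(bad, collapse = ", "))
  if (!log_scale && any(values < 0, na.rm = TRUE))
    stop("raw-scale intensities must be non-negative")
  names(platform) <- rownames(values)
  structure(list(values = values, platform = platform, log_scale = log_scale),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_scale) "log" else "raw"))
  tab <- table(x$platform)
  cat("platforms:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  nm <- sum(is.na(x$values))
  cat(sprintf("missing entries: %d (%.2f%%)\n", nm,
              100 * nm / length(x$values)))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' @param df Data frame with columns `sample_id` and `group` (levels `"WT"`
#'   and `"KO"`); any further numeric columns are treated as phenotype
#'   measurements (e.g. body size, body weight, blood glucose, hematocrit).
#' @return The validated data frame, classed `sample_info`.
#' @export
sample_info <- function(df) {
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample metadata needs `sample_id` and `group` columns")
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicate sample id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$group), c("WT", "KO"))
  if (length(bad))
    stop("group labels must be WT/KO; got: ", paste(bad, collapse = ", "))
  if (!all(c("WT", "KO") %in% df$group))
    stop("both WT and KO groups must be present")
  class(df) <- c("sample_info", "data.frame")
  df
}

#' Construct a feature-to-compound annotation table
#'
#' Features matched to more than one reference compound (coeluting
#' compounds) keep all their candidate names; they are flagged as not
#' uniquely identified and are excluded from pathway analysis.
#'
#' @param feature_id Character vector of feature ids (unique).
#' @param compounds List of character vectors, one per feature, each of
#'   length >= 1.
#' @return A data frame classed `annotation_table` with columns
#'   `feature_id`, `compounds` (list column), `n_compounds` and
#'   `uniquely_identified`.
#' @export
annotation_table <- function(feature_id, compounds) {
  feature_id <- as.character(feature_id)
  dup <- feature_id[duplicated(feature_id)]
  if (length(dup))
    stop("duplicate feature id in annotation: ",
         paste(unique(dup), collapse = ", "))
  if (length(compounds) != length(feature_id))
    stop("one compound list per feature required")
  n <- vapply(compounds, length, integer(1))
  if (any(n == 0L) || any(vapply(compounds, function(x) any(!nzchar(x)), logical(1))))
    stop("empty compound name for feature: ",
         paste(feature_id[n == 0L | vapply(compounds, function(x) any(!nzchar(x)), logical(1))],
               collapse = ", "))
  out <- data.frame(feature_id = feature_id, stringsAsFactors = FALSE)
  out$compounds <- unname(lapply(compounds, as.character))
  out$n_compounds <- n
  out$uniquely_identified <- n == 1L
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Construct a pathway membership database
#'
#' @param sets Named list of character vectors; names are pathway names
#'   (unique), elements the member compound names (deduplicated,
#'   non-empty).
#' @param category Optional character vector of pathway categories (e.g.
#'   `"Carbohydrate metabolism"`), recycled or named by pathway.
#' @return An object of class `pathway_db`.
#' @export
pathway_db <- function(sets, category = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all pathways must be named")
  dup <- names(sets)[duplicated(names(sets))]
  if (length(dup))
    stop("duplicate pathway name: ", paste(unique(dup), collapse = ", "))
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (any(vapply(sets, length, integer(1)) == 0L))
    stop("pathway with no members")
  if (is.null(category)) category <- rep("", length(sets))
  if (length(category) == 1L) category <- rep(category, length(sets))
  if (length(category) != length(sets))
    stop("one category per pathway required")
  names(category) <- names(sets)
  structure(list(sets = sets, category = category), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("pathway_db: %d pathways, member set sizes %d-%d\n",
              length(x$sets), min(sz), max(sz)))
  invisible(x)
}

# shared helper: split samples into WT / KO index vectors, validated
.group_indices <- function(m, info) {
  info <- sample_info(as.data.frame(info))
  missing_meta <- setdiff(colnames(m$values), info$sample_id)
  if (length(missing_meta))
    stop("samples without metadata: ", paste(missing_meta, collapse = ", "))
  grp <- info$group[match(colnames(m$values), info$sample_id)]
  idx <- list(wt = which(grp == "WT"), ko = which(grp == "KO"))
  if (length(idx$wt) < 2L || length(idx$ko) < 2L)
    stop("each group needs at least 2 samples in the matrix")
  idx
}
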