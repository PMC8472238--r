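#' Per-platform median normalization
#'
#' Within each acquisition platform, every sample's present intensities
#' are multiplied by one positive factor chosen so that the sample median
#' equals the median of all per-sample medians on that platform. This
#' equalizes sample loading separately for each platform while leaving
#' relative feature differences (and hence group effects) untouched.
#' Missing values are not altered.
#'
#' @param m A raw-scale [feature_matrix()].
#' @return A `feature_matrix` with an added `norm_factors` element: a
#'   platform x sample matrix of the scaling factors applied (`NA` where a
#'   platform has no features).
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$log_scale) stop("median_normalize expects raw-scale intensities")
  vals <- m$values
  plats <- unique(m$platform)
  factors <- matrix(NA_real_, length(plats), ncol(vals),
                    dimnames = list(plats, colnames(vals)))
  for (pl in plats) {
    rows <- which(m$platform == pl)
    sub <- vals[rows, , drop = FALSE]
    med <- apply(sub, 2L, stats::median, na.rm = TRUE)
    npresent <- colSums(!is.na(sub))
    if (any(npresent == 0L))
      stop("sample with no present values on platform ", pl, ": ",
           paste(colnames(sub)[npresent == 0L], collapse = ", "))
    if (any(med <= 0))
      stop("non-positive sample median on platform ", pl)
    target <- stats::median(med)
    f <- target / med
    vals[rows, ] <- sweep(sub, 2L, f, `*`)
    factors[pl, ] <- f
  }
  out <- feature_matrix(vals, m$platform, log_scale = FALSE)
  out$norm_factors <- factors
  out
}

#' Log-transform intensities
#'
#' Elementwise `log(value + pseudocount)` in the chosen base. The default
#' base 2 makes downstream group-mean differences directly interpretable
#' as log2 fold changes. Missing values are preserved.
#'
#' @param m A raw-scale [feature_matrix()].
#' @param base Logarithm base: 2 (default), `exp(1)` or 10.
#' @param pseudocount Non-negative offset added before the log; required
#'   (non-zero) when zero intensities are present.
#' @return A log-scale `feature_matrix` (carries `log_base` and any
#'   normalization factors forward).
#' @export
log_transform <- function(m, base = 2, pseudocount = 0) {
  stopifnot(inherits(m, "feature_matrix"))
  if (m$log_scale) stop("matrix is already log-scale")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(m$values + pseudocount <= 0, na.rm = TRUE))
    stop("zero intensities present; supply a positive `pseudocount`")
  vals <- log(m$values + pseudocount, base = base)
  out <- feature_matrix(vals, m$platform, log_scale = TRUE)
  out$log_base <- base
  out$norm_factors <- m$norm_factors
  out
}

#' Impute missing values by the per-feature mean
#'
#' Each missing cell of a feature is set to the mean of that feature's
#' present values across all samples (both groups pooled; the conservative
#' choice, as it biases group contrasts toward zero rather than away from
#' it). Runs on the log scale, after normalization. Setting
#' `groupwise = TRUE` with sample metadata imputes within genotype group
#' instead.
#'
#' @param m A log-scale [feature_matrix()].
#' @param info Optional [sample_info()]; required for `groupwise = TRUE`.
#' @param groupwise Impute within each group rather than from the grand
#'   mean.
#' @return A `normalized_matrix`: a `feature_matrix` with no missing
#'   entries plus provenance elements `imputed` (logical matrix flagging
#'   imputed cells) and `n_imputed`.
#' @export
impute_missing <- function(m, info = NULL, groupwise = FALSE) {
  stopifnot(inherits(m, "feature_matrix"))
  if (!m$log_scale)
    stop("impute_missing expects a log-scale matrix (run log_transform first)")
  vals <- m$values
  all_missing <- rowSums(!is.na(vals)) == 0L
  if (any(all_missing))
    stop("feature(s) entirely missing: ",
         paste(rownames(vals)[all_missing], collapse = ", "))
  imputed <- is.na(vals)
  if (groupwise) {
    if (is.null(info)) stop("groupwise imputation needs sample metadata")
    idx <- .group_indices(m, info)
    for (ix in idx) {
      sub <- vals[, ix, drop = FALSE]
      rm_ <- rowMeans(sub, na.rm = TRUE)
      if (any(is.nan(rm_) & rowSums(is.na(sub)) > 0L))
        stop("feature entirely missing within one group; use grand-mean imputation")
      miss <- which(is.na(sub), arr.ind = TRUE)
      sub[miss] <- rm_[miss[, 1L]]
      vals[, ix] <- sub
    }
  } else {
    rm_ <- rowMeans(vals, na.rm = TRUE)
    miss <- which(imputed, arr.ind = TRUE)
    vals[miss] <- rm_[miss[, 1L]]
  }
  out <- feature_matrix(vals, m$platform, log_scale = TRUE)
  out$log_base <- m$log_base
  out$norm_factors <- m$norm_factors
  out$imputed <- imputed
  out$n_imputed <- sum(imputed)
  class(out) <- c("normalized_matrix", class(out))
  out
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: per-platform median normalization, log transform,
#' per-feature mean imputation.
#'
#' @inheritParams log_transform
#' @inheritParams impute_missing
#' @return A `normalized_matrix` ready for [diff_test()].
#' @export
preprocess <- function(m, base = 2, pseudocount = 0, info = NULL,
                       groupwise = FALSE) {
  impute_missing(log_transform(median_normalize(m), base, pseudocount),
                 info = info, groupwise = groupwise)
}

#' Write preprocessing provenance
#'
#' Serializes the normalization factors and the coordinates of imputed
#' cells as TSVs next to the analysis results.
#'
#' @param m A `normalized_matrix`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_provenance <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "norm_factors.tsv")
  nf <- m$norm_factors
  if (is.null(nf)) nf <- matrix(numeric(0), 0, 0)
  utils::write.table(data.frame(platform = rownames(nf), nf,
                                check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "imputed_cells.tsv")
  idx <- which(m$imputed, arr.ind = TRUE)
  utils::write.table(
    data.frame(feature_id = rownames(m$values)[idx[, 1L]],
               sample_id = colnames(m$values)[idx[, 2L]]),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(norm_factors = p1, imputed_cells = p2))
}
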