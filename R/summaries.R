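#' PCA sample scores
#'
#' Samples are observations and features variables; features are centered
#' but not scaled (intensities already share a common log scale).
#' Components come from the singular value decomposition; explained
#' variance percentages derive from the squared singular values. Signs
#' follow a deterministic convention: within each component the loading
#' of largest magnitude is positive.
#'
#' @param m A complete log-scale [feature_matrix()] (or plain matrix,
#'   features x samples).
#' @param features Optional character vector restricting to a feature
#'   subset (e.g. identified metabolites only).
#' @return A list classed `pca_result` with `scores` (samples x
#'   components) and `explained_pct`.
#' @export
pca_scores <- function(m, features = NULL) {
  vals <- if (inherits(m, "feature_matrix")) m$values else m
  if (!is.null(features)) vals <- vals[features, , drop = FALSE]
  if (ncol(vals) < 3L) stop("PCA needs at least 3 samples")
  if (anyNA(vals)) stop("matrix contains missing values; impute first")
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2L, flip, `*`)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, explained_pct = expl),
            class = "pca_result")
}

#' Volcano table
#'
#' Per-metabolite log2 fold change, `-log10` adjusted p-value and a
#' significance flag (`adjP < alpha`, strict). The fold-change guide-line
#' positions are recorded in the attributes for plotting.
#'
#' @param diff A `diff_result` data frame.
#' @param alpha Significance threshold on the adjusted p-value (default
#'   0.05).
#' @param fc_lines Positions of vertical fold-change guides (default
#'   `c(-1, 1)`).
#' @return A data frame with `feature_id`, `compound` (if present),
#'   `logFC`, `neg_log10_adjP`, `significant`.
#' @export
volcano_table <- function(diff, alpha = 0.05, fc_lines = c(-1, 1)) {
  out <- data.frame(feature_id = diff$feature_id,
                    logFC = diff$logFC,
                    neg_log10_adjP = -log10(diff$adjP),
                    significant = diff$adjP < alpha,
                    stringsAsFactors = FALSE)
  if (!is.null(diff$compound)) out$compound <- diff$compound
  attr(out, "alpha") <- alpha
  attr(out, "fc_lines") <- fc_lines
  out
}

#' Hierarchically clustered heatmap ordering
#'
#' Rows (features) are standardized to zero mean and unit variance, then
#' rows and columns are clustered by average-linkage hierarchical
#' clustering of Euclidean distances. Rows and columns are sorted by id
#' before clustering so the result is invariant to input order; leaf
#' orders are the deterministic dendrogram orders of that canonical
#' input.
#'
#' @param m A complete matrix (features x samples) or
#'   [feature_matrix()] restricted to the features of interest (e.g. the
#'   significantly deregulated metabolites).
#' @return A list classed `heatmap_order` with `row_order`, `col_order`
#'   (ids in display order), `row_tree`, `col_tree` (`hclust` objects)
#'   and `values` (the standardized matrix, canonical id order).
#' @export
cluster_heatmap <- function(m) {
  vals <- if (inherits(m, "feature_matrix")) m$values else m
  if (nrow(vals) < 2L || ncol(vals) < 2L)
    stop("heatmap clustering needs at least 2 rows and 2 columns")
  if (anyNA(vals)) stop("matrix contains missing values; impute first")
  vals <- vals[order(rownames(vals)), order(colnames(vals)), drop = FALSE]
  sds <- apply(vals, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant feature cannot be standardized: ",
         paste(rownames(vals)[sds == 0], collapse = ", "))
  zs <- (vals - rowMeans(vals)) / sds
  row_tree <- stats::hclust(stats::dist(zs), method = "average")
  col_tree <- stats::hclust(stats::dist(t(zs)), method = "average")
  structure(list(row_order = rownames(zs)[row_tree$order],
                 col_order = colnames(zs)[col_tree$order],
                 row_tree = row_tree, col_tree = col_tree,
                 values = zs),
            class = "heatmap_order")
}

#' Group phenotype statistics
#'
#' Per phenotype measurement: group means, standard deviations with
#' divisor `n` (population convention), and the two-sided pooled-variance
#' two-sample t-test p-value on `n1 + n2 - 2` degrees of freedom. Samples
#' missing a measurement are dropped from that comparison.
#'
#' @param info A [sample_info()] data frame whose numeric columns beyond
#'   `sample_id`/`group` are the measurements.
#' @return A data frame, one row per measurement: `measurement`,
#'   `mean_WT`, `sd_WT`, `mean_KO`, `sd_KO`, `t`, `df`, `p`.
#' @export
phenotype_stats <- function(info) {
  info <- sample_info(as.data.frame(info))
  meas <- setdiff(names(info), c("sample_id", "group"))
  meas <- meas[vapply(info[meas], is.numeric, logical(1))]
  if (length(meas) == 0L) stop("no numeric phenotype measurements found")
  sd_n <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- lapply(meas, function(v) {
    w <- info[[v]][info$group == "WT"]
    k <- info[[v]][info$group == "KO"]
    w <- w[!is.na(w)]; k <- k[!is.na(k)]
    if (length(w) < 2L || length(k) < 2L)
      stop("measurement ", v, " needs >= 2 values per group")
    n1 <- length(w); n2 <- length(k); d <- n1 + n2 - 2L
    sp2 <- (sum((w - mean(w))^2) + sum((k - mean(k))^2)) / d
    t <- (mean(w) - mean(k)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    data.frame(measurement = v,
               mean_WT = mean(w), sd_WT = sd_n(w),
               mean_KO = mean(k), sd_KO = sd_n(k),
               t = t, df = d, p = 2 * stats::pt(-abs(t), d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
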