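#' Specification of a synthetic two-group metabolomics dataset
#'
#' Defines the generative model used for calibration and power studies:
#' per-feature log2 baselines, scaled-inverse-chi-square variances,
#' pathway-coherent group shifts with per-metabolite jitter, multi-platform
#' feature tags, and completely-at-random missingness. Defaults emulate
#' the structure of a two-genotype mouse cortex experiment (6 vs 6
#' samples; roughly a quarter of features annotated, a tenth of those
#' coeluting; dozens of partially overlapping pathways; effects up to a
#' few log2 units).
#'
#' @param n1,n2 Samples per group (default 6 each).
#' @param m_features Total feature count (default 600; use
#'   [full_scale_spec()] for the full-scale preset).
#' @param frac_annotated Fraction of features annotated to a compound
#'   (default 0.28).
#' @param frac_coeluting Fraction of annotated features matched to more
#'   than one compound (default 0.11); these are excluded from pathway
#'   sets downstream.
#' @param n_pathways Number of pathway sets (default 40).
#' @param pathway_sizes Inclusive size range of pathway member sets
#'   (default `c(3, 20)`).
#' @param frac_deregulated Fraction of pathways given a true group shift
#'   (default 0.5).
#' @param effect_range Magnitude range of the per-pathway mean log2 shift,
#'   drawn uniformly with random sign (default `c(0.5, 2.5)`).
#' @param effect_jitter_sd SD of the per-metabolite jitter around the
#'   pathway shift (default 0.3).
#' @param d0,s0_2 Variance hierarchy: per-feature variances are drawn as
#'   `s0_2 * d0 / rchisq(d0)` (default 4 and 0.04).
#' @param baseline_range Range of per-feature log2 grand means (default
#'   `c(11, 27)`).
#' @param missing_rate Completely-at-random missingness rate (default
#'   0.03).
#' @param platform_split Proportions of `uplc_pos`, `uplc_neg`, `gcms`
#'   features (default `c(0.49, 0.48, 0.03)`).
#' @param disjoint_pathways Force pathway member sets to be disjoint
#'   (errors when infeasible); used for calibration studies.
#' @param mnar Use intensity-dependent missingness (probability
#'   proportional to low baseline) instead of MCAR.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A list classed `synthetic_spec`.
#' @export
synthetic_spec <- function(n1 = 6L, n2 = 6L, m_features = 600L,
                           frac_annotated = 0.28, frac_coeluting = 0.11,
                           n_pathways = 40L, pathway_sizes = c(3L, 20L),
                           frac_deregulated = 0.5,
                           effect_range = c(0.5, 2.5),
                           effect_jitter_sd = 0.3,
                           d0 = 4, s0_2 = 0.04,
                           baseline_range = c(11, 27),
                           missing_rate = 0.03,
                           platform_split = c(0.49, 0.48, 0.03),
                           disjoint_pathways = FALSE,
                           mnar = FALSE,
                           seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n1 >= 2, n2 >= 2, m_features >= 20,
            frac_annotated >= 0, frac_annotated <= 1,
            frac_coeluting >= 0, frac_coeluting <= 1,
            frac_deregulated >= 0, frac_deregulated <= 1,
            missing_rate >= 0, missing_rate < 1,
            pathway_sizes[1] >= 3, d0 > 0, s0_2 > 0)
  class(spec) <- "synthetic_spec"
  spec
}

#' Full-scale synthetic preset
#'
#' The default [synthetic_spec()] scaled up to the dimensions of a real
#' untargeted cortex screen: 4143 features, 283 annotated, 32 coeluting.
#'
#' @param ... Overrides passed to [synthetic_spec()].
#' @export
full_scale_spec <- function(...) {
  spec <- synthetic_spec(m_features = 4143L,
                         frac_annotated = 283 / 4143,
                         frac_coeluting = 32 / 283, ...)
  spec
}

#' Generate a synthetic two-group metabolomics dataset
#'
#' Draws a complete dataset from a [synthetic_spec()]: per feature a
#' variance `sigma2 ~ s0_2 * d0 / chisq(d0)` and a baseline mean; WT
#' samples `N(mu, sigma2)` and KO samples `N(mu + delta, sigma2)` on the
#' log2 scale, where `delta` is the pathway-level shift plus jitter for
#' uniquely identified metabolites in deregulated pathways and zero
#' otherwise; raw-scale output `2^value` with missing entries masked.
#' Pathways may share compounds (as real pathway databases do); a
#' metabolite in several deregulated pathways takes the shift of the
#' first one.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `matrix` (raw-scale [feature_matrix()] with
#'   missing values), `info` ([sample_info()]), `annotation`
#'   ([annotation_table()]), `pathways` ([pathway_db()]) and `truth`
#'   (per-pathway `deregulated`/`shift`, per-feature `delta`/`sigma2`,
#'   and the missingness mask).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$m_features
  n <- spec$n1 + spec$n2
  feat <- sprintf("f%04d", seq_len(m))
  samp <- c(sprintf("WT_%02d", seq_len(spec$n1)),
            sprintf("KO_%02d", seq_len(spec$n2)))
  group <- rep(c("WT", "KO"), c(spec$n1, spec$n2))

  n_ann <- round(spec$frac_annotated * m)
  n_coel <- round(spec$frac_coeluting * n_ann)
  n_uniq <- n_ann - n_coel
  ann_idx <- sort(sample.int(m, n_ann))
  coel_idx <- sort(sample(ann_idx, n_coel))
  uniq_idx <- setdiff(ann_idx, coel_idx)
  compounds <- sprintf("cmpd_%03d", seq_len(n_uniq))
  comp_of <- stats::setNames(compounds, feat[uniq_idx])

  # pathway membership over uniquely identified compounds
  sz_range <- seq(spec$pathway_sizes[1], spec$pathway_sizes[2])
  sizes <- sz_range[sample.int(length(sz_range), spec$n_pathways,
                               replace = TRUE)]
  if (spec$disjoint_pathways && sum(sizes) > n_uniq)
    stop("disjoint pathways infeasible: ", sum(sizes),
         " memberships requested but only ", n_uniq, " unique compounds")
  if (max(sizes) > n_uniq)
    stop("pathway size exceeds available unique compounds")
  pw_names <- sprintf("pathway_%02d", seq_len(spec$n_pathways))
  categories <- c("Carbohydrate metabolism", "Energy metabolism",
                  "Lipid metabolism", "Nucleotide metabolism",
                  "Amino acid metabolism",
                  "Metabolism of cofactors and vitamins")
  if (spec$disjoint_pathways) {
    pool <- sample(compounds)
    stops <- cumsum(sizes)
    sets <- lapply(seq_along(sizes), function(i)
      pool[(c(0, stops)[i] + 1):stops[i]])
  } else {
    sets <- lapply(sizes, function(s) sample(compounds, s))
  }
  names(sets) <- pw_names
  db <- pathway_db(sets, sample(categories, spec$n_pathways, replace = TRUE))

  # pathway-level deregulation, then per-metabolite true shifts
  n_dereg <- round(spec$frac_deregulated * spec$n_pathways)
  dereg <- seq_len(spec$n_pathways) <= n_dereg   # first n_dereg pathways
  shift <- numeric(spec$n_pathways)
  shift[dereg] <- stats::runif(n_dereg, spec$effect_range[1],
                               spec$effect_range[2]) *
    sample(c(-1, 1), n_dereg, replace = TRUE)
  delta <- stats::setNames(numeric(m), feat)
  for (cp in compounds) {
    in_dereg <- which(dereg & vapply(sets, function(s) cp %in% s, logical(1)))
    if (length(in_dereg)) {
      fid <- names(comp_of)[match(cp, comp_of)]
      delta[fid] <- shift[in_dereg[1L]] +
        stats::rnorm(1, 0, spec$effect_jitter_sd)
    }
  }

  sigma2 <- spec$s0_2 * spec$d0 / stats::rchisq(m, df = spec$d0)
  mu <- stats::runif(m, spec$baseline_range[1], spec$baseline_range[2])
  eps <- matrix(stats::rnorm(m * n), m, n) * sqrt(sigma2)
  logvals <- mu + eps
  logvals[, group == "KO"] <- logvals[, group == "KO"] + delta
  raw <- 2^logvals
  dimnames(raw) <- list(feat, samp)

  if (spec$mnar) {
    pr <- spec$missing_rate * 2 *
      (1 - (mu - min(mu)) / (max(mu) - min(mu) + 1e-12))
    mask <- matrix(stats::runif(m * n), m, n) < pr
  } else {
    mask <- matrix(stats::runif(m * n), m, n) < spec$missing_rate
  }
  # never blank out a whole feature
  allgone <- rowSums(!mask) == 0L
  mask[allgone, 1L] <- FALSE
  raw[mask] <- NA_real_

  plat_counts <- diff(c(0L, round(cumsum(spec$platform_split) /
                                    sum(spec$platform_split) * m)))
  platform <- sample(rep(c("uplc_pos", "uplc_neg", "gcms"),
                         times = plat_counts))
  ann_comp <- vector("list", n_ann)
  names(ann_comp) <- feat[ann_idx]
  for (fid in feat[uniq_idx]) ann_comp[[fid]] <- unname(comp_of[fid])
  for (i in seq_along(coel_idx)) {
    fid <- feat[coel_idx[i]]
    k <- sample(2:3, 1)
    ann_comp[[fid]] <- sprintf("coel_%03d%s", i, letters[seq_len(k)])
  }

  info <- sample_info(data.frame(sample_id = samp, group = group,
                                 stringsAsFactors = FALSE))
  list(matrix = feature_matrix(raw, platform),
       info = info,
       annotation = annotation_table(feat[ann_idx], ann_comp),
       pathways = db,
       truth = list(pathway = data.frame(pathway = pw_names,
                                         deregulated = dereg,
                                         shift = shift,
                                         stringsAsFactors = FALSE),
                    feature = data.frame(feature_id = feat,
                                         delta = unname(delta),
                                         sigma2 = sigma2,
                                         stringsAsFactors = FALSE),
                    missing_mask = mask),
       spec = spec)
}

#' Write all artifacts of a synthetic dataset
#'
#' Emits the intensity table, sample metadata, annotation table, pathway
#' GMT and ground-truth tables into a directory, in the same formats the
#' pipeline reads back.
#'
#' @param ds A dataset from [generate_dataset()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    matrix = file.path(dir, "intensities.tsv"),
    info = file.path(dir, "samples.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    gmt = file.path(dir, "pathways.gmt"),
    truth_pathway = file.path(dir, "truth_pathways.tsv"),
    truth_feature = file.path(dir, "truth_features.tsv"))
  write_feature_matrix(ds$matrix, paths["matrix"])
  utils::write.table(as.data.frame(ds$info), paths["info"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_annotation(ds$annotation, paths["annotation"])
  write_gmt(ds$pathways, paths["gmt"])
  utils::write.table(ds$truth$pathway, paths["truth_pathway"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$truth$feature, paths["truth_feature"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
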