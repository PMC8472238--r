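#' Map pathways to measured, uniquely identified metabolites
#'
#' Intersects each pathway's compound members with the uniquely
#' identified, tested compounds; only sets with at least `min_size`
#' members are kept (smaller pathways carry too little signal to test).
#' Coeluting (multiply annotated) features never enter a set.
#'
#' @param db A [pathway_db()].
#' @param annotation An [annotation_table()].
#' @param tested Character vector of feature ids that were actually
#'   tested (e.g. `diff$feature_id`).
#' @param min_size Minimum number of member metabolites (default 3).
#' @return A list of pathway sets, each a list with `name`, `category`
#'   and `feature_ids`; the number of discarded pathways is attached as
#'   attribute `n_discarded`.
#' @export
build_pathway_sets <- function(db, annotation, tested, min_size = 3L) {
  uniq <- annotation[annotation$uniquely_identified &
                       annotation$feature_id %in% tested, ]
  compound <- vapply(uniq$compounds, `[[`, character(1), 1L)
  sets <- lapply(names(db$sets), function(nm) {
    ids <- uniq$feature_id[compound %in% db$sets[[nm]]]
    list(name = nm, category = unname(db$category[[nm]]), feature_ids = ids)
  })
  keep <- vapply(sets, function(s) length(s$feature_ids) >= min_size,
                 logical(1))
  out <- sets[keep]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Mean-z pathway deregulation statistic
#'
#' The single pathway score: the arithmetic mean of the member
#' metabolites' standard-normal-equivalent z-scores. Its sign gives the
#' pathway's direction of deregulation.
#'
#' @param z Named numeric vector of per-metabolite z-scores.
#' @param set A pathway set from [build_pathway_sets()].
#' @return The mean z-score of the set's members.
#' @export
pathway_score <- function(z, set) {
  miss <- setdiff(set$feature_ids, names(z))
  if (length(miss))
    stop("set member without a z-score: ", paste(miss, collapse = ", "))
  mean(z[set$feature_ids])
}

#' Count pathway contributors beyond a z threshold
#'
#' Metabolites whose |z| exceeds the threshold (default `sqrt(2)`,
#' strict inequality) are counted as driving the pathway's up- or
#' downregulation.
#'
#' @inheritParams pathway_score
#' @param threshold Positive contributor threshold (default `sqrt(2)`).
#' @return Integer vector `c(n_up, n_down)`.
#' @export
count_contributors <- function(z, set, threshold = sqrt(2)) {
  stopifnot(threshold > 0)
  zz <- z[set$feature_ids]
  c(n_up = sum(zz > threshold), n_down = sum(zz < -threshold))
}

#' Reduce samples to effect/residual rotation coordinates
#'
#' For each feature the `n`-dimensional sample vector is projected onto
#' an orthonormal basis of the two-group model space complement: one
#' effect coordinate `u = logFC / sqrt(1/n1 + 1/n2)` along the
#' (intercept-orthogonal) group contrast, and `d = n1 + n2 - 2` residual
#' coordinates whose squared norm equals `d * s2`. The unmoderated t is
#' recoverable as `u / sqrt(||r||^2 / d)`. Random re-orientation of these
#' coordinates generates the rotation null.
#'
#' @param m A complete log-scale [feature_matrix()].
#' @param info A [sample_info()] table.
#' @return A list with `Y` (features x (d+1) coordinate matrix, effect
#'   first), `d` (residual df) and `design` (`n1`, `n2`).
#' @export
make_rotation_frame <- function(m, info) {
  stopifnot(inherits(m, "feature_matrix"))
  if (anyNA(m$values))
    stop("matrix contains missing values; impute first")
  idx <- .group_indices(m, info)
  n1 <- length(idx$wt); n2 <- length(idx$ko)
  n <- n1 + n2
  d <- n - 2L
  # contrast direction orthogonal to the intercept, unit length
  v <- numeric(n)
  v[idx$ko] <- 1 / n2
  v[idx$wt] <- -1 / n1
  v <- v / sqrt(sum(v^2))        # ||v||^2 was 1/n1 + 1/n2
  X <- cbind(rep(1, n), v)
  Qfull <- qr.Q(qr(X), complete = TRUE)
  basis <- cbind(v, Qfull[, 3:n, drop = FALSE])   # effect + residual space
  Y <- m$values %*% basis
  colnames(Y) <- c("u", paste0("r", seq_len(d)))
  list(Y = Y, d = d, design = c(n1 = n1, n2 = n2))
}

#' Rotation configuration
#'
#' @param B Number of random rotations (default 9999; at least 99).
#' @param seed Optional integer seed fixing the rotation draws.
#' @param contributor_threshold Contributor |z| threshold (default
#'   `sqrt(2)`).
#' @param alternative `"directional"` (two-sided on the signed mean-z,
#'   default) or `"mixed"` (one-sided on the mean squared z; sensitive to
#'   deregulation with mixed signs).
#' @return A list classed `rotation_config`.
#' @export
rotation_config <- function(B = 9999L, seed = NULL,
                            contributor_threshold = sqrt(2),
                            alternative = c("directional", "mixed")) {
  B <- as.integer(B)
  if (B < 99L) stop("at least 99 rotations are required")
  if (contributor_threshold <= 0) stop("contributor threshold must be > 0")
  structure(list(B = B, seed = seed,
                 contributor_threshold = contributor_threshold,
                 alternative = match.arg(alternative)),
            class = "rotation_config")
}

#' Rotation-based pathway deregulation test
#'
#' ROAST-style Monte-Carlo test of each pathway's mean-z statistic. Every
#' rotation draws one random unit vector in the (d+1)-dimensional
#' effect/residual space, shared across all features, which preserves
#' inter-metabolite correlation. The rotated effect and residual variance
#' are pushed through the same moderation and z-transform as the observed
#' data, with the variance prior held fixed at its estimate from the
#' observed data. Rotation p-values cannot fall below `1/(B+1)`; tied
#' rotated scores count as exceeding the observed one (conservative).
#'
#' @param frame A rotation frame from [make_rotation_frame()].
#' @param sets Pathway sets from [build_pathway_sets()].
#' @param prior A fixed `ebayes_prior` (use `list(d0 = 0, s0_2 = 0)` for
#'   no moderation).
#' @param cfg A [rotation_config()].
#' @return A data frame classed `pathway_result`, one row per set:
#'   `pathway`, `n_features`, `n_down`, `n_up`, `direction`, `p`, `adjP`,
#'   `group`. The observed scores are attached as attribute `scores`.
#' @export
roast_test <- function(frame, sets, prior, cfg = rotation_config()) {
  stopifnot(inherits(cfg, "rotation_config"))
  if (length(sets) == 0L) {
    out <- data.frame(pathway = character(0), n_features = integer(0),
                      n_down = integer(0), n_up = integer(0),
                      direction = character(0), p = numeric(0),
                      adjP = numeric(0), group = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("pathway_result", "data.frame")
    return(out)
  }
  members <- unique(unlist(lapply(sets, `[[`, "feature_ids")))
  miss <- setdiff(members, rownames(frame$Y))
  if (length(miss))
    stop("set member not in rotation frame: ", paste(miss, collapse = ", "))
  Y <- frame$Y[members, , drop = FALSE]
  d <- frame$d
  n1 <- frame$design[["n1"]]; n2 <- frame$design[["n2"]]
  scale2 <- 1 / n1 + 1 / n2
  tot2 <- rowSums(Y^2)

  # moderated z from rotated effect coordinates (matrix of u, one column
  # per rotation; first column = observed)
  z_of_u <- function(U) {
    s2 <- pmax((tot2 - U^2) / d, 0)
    if (is.infinite(prior$d0)) {
      s2_post <- matrix(prior$s0_2, nrow(U), ncol(U))
      dft <- Inf
    } else {
      s2_post <- (prior$d0 * prior$s0_2 + d * s2) / (prior$d0 + d)
      dft <- d + prior$d0
    }
    se <- sqrt(s2_post * scale2)
    t <- ifelse(se == 0, 0, U / se)
    matrix(t_to_z(t, dft), nrow(U), ncol(U), dimnames = dimnames(U))
  }

  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  R <- matrix(stats::rnorm((d + 1L) * cfg$B), d + 1L, cfg$B)
  R <- sweep(R, 2L, sqrt(colSums(R^2)), `/`)
  U <- cbind(Y[, 1L, drop = FALSE], Y %*% R)   # members x (B+1), obs first
  Z <- z_of_u(U)
  z_obs <- stats::setNames(Z[, 1L], rownames(Z))

  stat <- switch(cfg$alternative,
                 directional = function(zz) zz,
                 mixed = function(zz) zz^2)
  res <- lapply(sets, function(s) {
    S <- colMeans(stat(Z[s$feature_ids, , drop = FALSE]))
    S_obs <- S[1L]; S_rot <- S[-1L]
    if (cfg$alternative == "directional") {
      p_up <- (sum(S_rot >= S_obs) + 1) / (cfg$B + 1)
      p_down <- (sum(S_rot <= S_obs) + 1) / (cfg$B + 1)
      p <- min(1, 2 * min(p_up, p_down))
    } else {
      p <- (sum(S_rot >= S_obs) + 1) / (cfg$B + 1)
    }
    cc <- count_contributors(z_obs, s, cfg$contributor_threshold)
    data.frame(pathway = s$name,
               n_features = length(s$feature_ids),
               n_down = unname(cc["n_down"]), n_up = unname(cc["n_up"]),
               direction = if (mean(z_obs[s$feature_ids]) >= 0) "Up" else "Down",
               p = p, group = s$category, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjP <- bh_adjust(out$p)
  out <- out[, c("pathway", "n_features", "n_down", "n_up", "direction",
                 "p", "adjP", "group")]
  rownames(out) <- NULL
  attr(out, "scores") <- z_obs
  attr(out, "B") <- cfg$B
  attr(out, "p_floor") <- 1 / (cfg$B + 1)
  class(out) <- c("pathway_result", "data.frame")
  out
}
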