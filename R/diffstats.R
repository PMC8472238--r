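#' Per-feature two-group summary statistics
#'
#' For every feature: the KO minus WT difference of group means (the log2
#' fold change when the matrix is on the log2 scale), the grand-mean
#' average expression, and the pooled within-group variance on
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param m A complete (imputed) log-scale [feature_matrix()].
#' @param info A [sample_info()] table covering all samples.
#' @return A list with `logFC`, `aveExpr`, `s2` (named numeric vectors),
#'   `df` (residual degrees of freedom, scalar) and `design`
#'   (`n1` = WT count, `n2` = KO count).
#' @export
fit_two_group <- function(m, info) {
  stopifnot(inherits(m, "feature_matrix"))
  if (anyNA(m$values))
    stop("matrix contains missing values; impute first")
  idx <- .group_indices(m, info)
  n1 <- length(idx$wt); n2 <- length(idx$ko)
  mw <- rowMeans(m$values[, idx$wt, drop = FALSE])
  mk <- rowMeans(m$values[, idx$ko, drop = FALSE])
  ssw <- rowSums((m$values[, idx$wt, drop = FALSE] - mw)^2)
  ssk <- rowSums((m$values[, idx$ko, drop = FALSE] - mk)^2)
  d <- n1 + n2 - 2L
  list(logFC = mk - mw,
       aveExpr = rowMeans(m$values),
       s2 = (ssw + ssk) / d,
       df = d,
       design = c(n1 = n1, n2 = n2))
}

# Newton inversion of the trigamma function (monotone decreasing on
# (0, Inf)); used by the moment-matching prior estimator.
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Estimate the variance-shrinkage prior by moment matching
#'
#' Models per-feature residual variances as draws from a scaled inverse
#' chi-square distribution with prior degrees of freedom `d0` and prior
#' variance `s0_2`, and estimates both by matching the mean and variance
#' of the log variances: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`,
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` is solved for `d0`
#' on the trigamma scale (Newton iteration); a non-positive right-hand
#' side means the variances are no more dispersed than sampling noise
#' alone, giving `d0 = Inf` and complete shrinkage to
#' `s0_2 = exp(mean(e))`.
#'
#' @param s2 Numeric vector of residual variances (>= 10 values).
#' @param df Residual degrees of freedom (scalar or per-feature vector).
#' @return A list with `d0` (possibly `Inf`) and `s0_2`, classed
#'   `ebayes_prior`.
#' @export
estimate_prior <- function(s2, df) {
  s2 <- as.numeric(s2)
  if (length(df) == 1L) df <- rep(df, length(s2))
  ok <- df >= 1
  if (sum(ok) < 10L)
    stop("at least 10 features with df >= 1 are required to estimate the prior")
  s2 <- s2[ok]; df <- df[ok]
  if (all(s2 == 0))
    stop("all residual variances are zero; data degenerate")
  # guard exact zeros the way a log-based moment fit must
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (evar <= 0) {
    # variances no more spread than sampling noise: complete shrinkage;
    # the arithmetic mean is the natural pooled estimate here (the
    # log-scale back-transform is biased upward in this degenerate case)
    d0 <- Inf
    s0_2 <- mean(s2)
  } else {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_2 = s0_2), class = "ebayes_prior")
}

#' @export
print.ebayes_prior <- function(x, ...) {
  cat(sprintf("ebayes_prior: d0 = %s, s0_2 = %.6g\n",
              format(x$d0, digits = 4), x$s0_2))
  invisible(x)
}

#' Moderated two-sample t-statistics
#'
#' Shrinks each feature's residual variance toward the prior,
#' `s2_post = (d0*s0_2 + d*s2) / (d0 + d)`, and tests the group contrast
#' with `t = logFC / (sqrt(s2_post) * sqrt(1/n1 + 1/n2))` on
#' `d + d0` total degrees of freedom (standard normal in the `d0 = Inf`
#' limit). `d0 = 0` recovers the ordinary pooled two-sample t-test.
#'
#' @param logFC Numeric vector of group-mean differences.
#' @param s2 Residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @param prior An `ebayes_prior` (or list with `d0`, `s0_2`).
#' @param n1,n2 Group sample sizes.
#' @return A list with `t`, `df_total`, `p` (two-sided) and `s2_post`.
#' @export
moderated_t <- function(logFC, s2, df, prior, n1, n2) {
  d0 <- prior$d0; s0_2 <- prior$s0_2
  if (is.infinite(d0)) {
    s2_post <- stats::setNames(rep(s0_2, length(logFC)), names(logFC))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_2 + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  if (any(se == 0 & logFC != 0))
    stop("zero posterior variance with non-zero effect: statistic infinite")
  t <- ifelse(se == 0, 0, logFC / se)
  p <- 2 * stats::pt(-abs(t), df = df_total)
  list(t = t, df_total = df_total, p = p, s2_post = s2_post)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `adj_(i) = min_{j>=i}(p_(j) * m / j)` capped at 1, returned in the
#' input order. Ties are handled by a stable sort so results do not
#' depend on input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Convert moderated t-statistics to standard-normal equivalents
#'
#' Maps each t through its cumulative distribution and back through the
#' normal quantile, `z = qnorm(pt(t, df))`, evaluated on the smaller tail
#' in log space so extreme statistics do not saturate to `Inf`. `|z|` is
#' clamped at 37 (beyond double-precision tail resolution). These z-scores
#' are the per-metabolite inputs of the pathway deregulation statistic.
#'
#' @param t Numeric vector of t-statistics.
#' @param df Total degrees of freedom (scalar or vector; `Inf` gives the
#'   identity).
#' @return Numeric vector of z-scores, same sign as `t`.
#' @export
t_to_z <- function(t, df) {
  logp <- stats::pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE)
  z <- -stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  z <- pmin(abs(z), 37)
  sign(t) * z
}

#' Per-metabolite differential abundance analysis
#'
#' The full inference chain: group fits, moment-matched variance prior,
#' moderated t-statistics, BH adjustment and z-score transformation. The
#' number of tests entering the BH correction (`m`) is the number of rows
#' of the supplied matrix; restrict the matrix (e.g. to uniquely
#' identified metabolites) beforehand if a smaller family is intended.
#'
#' @param m A complete log-scale [feature_matrix()] (typically from
#'   [preprocess()]).
#' @param info A [sample_info()] table.
#' @param prior Optional fixed `ebayes_prior`; estimated from the data
#'   when `NULL`. Use `list(d0 = 0)` to disable shrinkage.
#' @param annotation Optional [annotation_table()]; when given, a
#'   `compound` column is filled for uniquely identified features.
#' @return A data frame classed `diff_result` with one row per feature:
#'   `feature_id`, `compound`, `logFC`, `aveExpr`, `t`, `df_total`, `p`,
#'   `adjP`, `z`. The estimated prior and the BH family size are attached
#'   as attributes `prior` and `m_tests`.
#' @export
diff_test <- function(m, info, prior = NULL, annotation = NULL) {
  fit <- fit_two_group(m, info)
  if (is.null(prior)) {
    prior <- estimate_prior(fit$s2, fit$df)
  } else if (!is.null(prior$d0) && prior$d0 == 0) {
    prior <- list(d0 = 0, s0_2 = if (is.null(prior$s0_2)) 0 else prior$s0_2)
  }
  mt <- moderated_t(fit$logFC, fit$s2, fit$df, prior,
                    fit$design[["n1"]], fit$design[["n2"]])
  out <- data.frame(
    feature_id = names(fit$logFC),
    compound = NA_character_,
    logFC = unname(fit$logFC),
    aveExpr = unname(fit$aveExpr),
    t = unname(mt$t),
    df_total = mt$df_total,
    p = unname(mt$p),
    adjP = bh_adjust(mt$p),
    z = unname(t_to_z(mt$t, mt$df_total)),
    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    uniq <- annotation[annotation$uniquely_identified, ]
    hit <- match(out$feature_id, uniq$feature_id)
    ok <- !is.na(hit)
    out$compound[ok] <- vapply(uniq$compounds[hit[ok]], `[[`, character(1), 1L)
  }
  attr(out, "prior") <- prior
  attr(out, "m_tests") <- nrow(out)
  class(out) <- c("diff_result", "data.frame")
  out
}
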