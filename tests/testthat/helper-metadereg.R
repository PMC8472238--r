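# Small in-code fixtures shared across test files.

# A tiny raw-scale matrix: 3 features x 4 samples, one missing cell.
tiny_matrix <- function() {
  vals <- matrix(c(10, 20, 30, 40,
                   5, NA, 15, 20,
                   8, 8, 8, 8), 3, 4, byrow = TRUE,
                 dimnames = list(c("f1", "f2", "f3"),
                                 c("w1", "w2", "k1", "k2")))
  feature_matrix(vals, c("uplc_pos", "uplc_neg", "gcms"))
}

tiny_info <- function() {
  sample_info(data.frame(sample_id = c("w1", "w2", "k1", "k2"),
                         group = c("WT", "WT", "KO", "KO"),
                         stringsAsFactors = FALSE))
}

# Complete log-scale matrix from explicit per-feature WT/KO values.
log_matrix <- function(wt, ko, ids = NULL) {
  wt <- as.matrix(wt); ko <- as.matrix(ko)
  vals <- cbind(wt, ko)
  if (is.null(ids)) ids <- paste0("f", seq_len(nrow(vals)))
  dimnames(vals) <- list(ids, c(paste0("w", seq_len(ncol(wt))),
                                paste0("k", seq_len(ncol(ko)))))
  feature_matrix(vals, "gcms", log_scale = TRUE)
}

info_for <- function(m) {
  ids <- colnames(m$values)
  sample_info(data.frame(sample_id = ids,
                         group = ifelse(startsWith(ids, "w"), "WT", "KO"),
                         stringsAsFactors = FALSE))
}

# Random complete log-scale two-group matrix.
random_log_matrix <- function(m = 50, n1 = 4, n2 = 4, effect = 0, sd = 1,
                              seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(m * (n1 + n2), sd = sd), m, n1 + n2)
  vals[, (n1 + 1):(n1 + n2)] <- vals[, (n1 + 1):(n1 + n2)] + effect
  dimnames(vals) <- list(sprintf("f%03d", seq_len(m)),
                         c(paste0("w", seq_len(n1)), paste0("k", seq_len(n2))))
  feature_matrix(vals, "uplc_pos", log_scale = TRUE)
}

# Brute-force BH oracle: the adjusted p of test i is the smallest level
# alpha at which the step-up procedure rejects i; candidate levels are
# the finitely many alphas where the rejection set can change.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  cand <- sort(unique(pmin(1, p[ord] * m / seq_len(m))))
  rejected_at <- function(alpha) {
    ps <- sort(p)
    k <- which(ps <= seq_len(m) * alpha / m + 1e-12)
    if (length(k) == 0L) return(rep(FALSE, m))
    p <= ps[max(k)]
  }
  vapply(seq_len(m), function(i) {
    hits <- cand[vapply(cand, function(a) rejected_at(a)[i], logical(1))]
    if (length(hits)) min(hits) else 1
  }, numeric(1))
}
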