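make_sets <- function(...) {
  lst <- list(...)
  lapply(seq_along(lst), function(i)
    list(name = paste0("P", i), category = "", feature_ids = lst[[i]]))
}

test_that("pathway sets keep only uniquely identified, sufficiently covered pathways", {
  ann <- annotation_table(c("f1", "f2", "f3", "f4", "f5"),
                          list("A", "B", "C", c("D", "D2"), "E"))
  db <- pathway_db(list(big = c("A", "B", "C"),
                        small = c("A", "B"),
                        coel = c("A", "B", "D")),
                   category = c("cat1", "cat2", "cat3"))
  sets <- build_pathway_sets(db, ann, tested = paste0("f", 1:5))
  nms <- vapply(sets, `[[`, character(1), "name")
  expect_equal(nms, "big")  # small has 2 members; coel only 2 unique ones
  expect_equal(sets[[1]]$feature_ids, c("f1", "f2", "f3"))
  expect_equal(attr(sets, "n_discarded"), 2L)
  # the coeluting feature f4 never enters any set
  expect_false("f4" %in% unlist(lapply(sets, `[[`, "feature_ids")))
  # untested features are excluded too
  sets2 <- build_pathway_sets(db, ann, tested = c("f1", "f2"))
  expect_length(sets2, 0L)
})

test_that("pathway score is the mean member z and contributors use strict thresholds", {
  z <- c(f1 = 2.0, f2 = -1.0, f3 = 1.5, f4 = sqrt(2), f5 = -3, f6 = -2, f7 = 5)
  s <- make_sets(c("f1", "f2", "f3"))[[1]]
  expect_equal(pathway_score(z, s), mean(c(2, -1, 1.5)))
  expect_equal(unname(count_contributors(z, s)), c(2, 0))

  single <- make_sets("f3")[[1]]
  expect_equal(pathway_score(z, single), 1.5)

  expect_equal(pathway_score(c(a = 0, b = 0), make_sets(c("a", "b"))[[1]]), 0)
  # exactly sqrt(2) is not a contributor (strict inequality)
  expect_equal(unname(count_contributors(z, make_sets("f4")[[1]])), c(0, 0))
  expect_equal(unname(count_contributors(z, make_sets(c("f5", "f6", "f7"))[[1]])),
               c(1, 2))
  expect_error(pathway_score(z, make_sets("missing")[[1]]), "missing")
})

test_that("rotation frame encodes effect and residual coordinates exactly", {
  m <- log_matrix(rbind(c(1, 2, 3)), rbind(c(4, 5, 6)))
  fr <- make_rotation_frame(m, info_for(m))
  expect_equal(fr$d, 4L)
  expect_equal(unname(fr$Y[1, "u"]), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(sum(fr$Y[1, -1]^2), 4, tolerance = 1e-10)

  # zero-variance zero-effect feature maps to the zero vector (after
  # centering: constant feature has all coordinates 0 except intercept,
  # which the frame excludes)
  m2 <- log_matrix(rbind(c(2, 2), c(1, 3)), rbind(c(2, 2), c(2, 4)))
  fr2 <- make_rotation_frame(m2, info_for(m2))
  expect_equal(unname(fr2$Y[1, ]), rep(0, fr2$d + 1))

  # reconstruction: u / sqrt(||r||^2 / d) is the unmoderated t
  m3 <- random_log_matrix(m = 30, n1 = 5, n2 = 4, effect = 1, seed = 10)
  fr3 <- make_rotation_frame(m3, info_for(m3))
  fit <- fit_two_group(m3, info_for(m3))
  t_frame <- fr3$Y[, 1] / sqrt(rowSums(fr3$Y[, -1]^2) / fr3$d)
  t_ref <- fit$logFC / sqrt(fit$s2 * (1 / 5 + 1 / 4))
  expect_equal(t_frame, t_ref, tolerance = 1e-10)
  # norms decompose: total sum of squares about the fitted means
  expect_equal(unname(rowSums(fr3$Y[, -1]^2)), unname(fit$s2 * fr3$d),
               tolerance = 1e-10)
})

test_that("rotation p-values respect Monte-Carlo bounds and are reproducible", {
  m <- random_log_matrix(m = 30, n1 = 6, n2 = 6, effect = 2, seed = 21)
  info <- info_for(m)
  fr <- make_rotation_frame(m, info)
  sets <- make_sets(rownames(m$values)[1:5], rownames(m$values)[6:10])
  prior <- list(d0 = 4, s0_2 = 1)
  cfg <- rotation_config(B = 499, seed = 13)
  r1 <- roast_test(fr, sets, prior, cfg)
  expect_true(all(r1$p >= 1 / 500 & r1$p <= 1))
  expect_true(all(r1$n_down + r1$n_up <= r1$n_features))
  expect_true(all(r1$direction %in% c("Up", "Down")))
  r2 <- roast_test(fr, sets, prior, cfg)
  expect_identical(r1, r2)

  expect_error(rotation_config(B = 50), "99")
  empty <- roast_test(fr, list(), prior, cfg)
  expect_equal(nrow(empty), 0L)
})

test_that("singleton-set rotation p matches the parametric moderated-t p", {
  m <- log_matrix(rbind(c(0.1, -0.4, 0.2, 0.05, -0.3, 0.25)),
                  rbind(c(0.9, 0.2, 0.8, 0.4, 1.1, 0.3)))
  info <- info_for(m)
  fr <- make_rotation_frame(m, info)
  fit <- fit_two_group(m, info)
  par_p <- moderated_t(fit$logFC, fit$s2, fit$df, list(d0 = 0, s0_2 = 0),
                       6, 6)$p
  B <- 20000
  r <- roast_test(fr, make_sets("f1"), list(d0 = 0, s0_2 = 0),
                  rotation_config(B = B, seed = 5))
  mc_se <- sqrt(par_p * (1 - par_p) / B) * 2  # directional doubling
  expect_lt(abs(r$p - par_p), 3 * mc_se + 2 / (B + 1))
})

test_that("doubling the rotation count moves p-values by a few MC standard errors only", {
  m <- random_log_matrix(m = 20, n1 = 6, n2 = 6, effect = 0.9, seed = 31)
  fr <- make_rotation_frame(m, info_for(m))
  sets <- make_sets(rownames(m$values)[1:4], rownames(m$values)[5:12])
  prior <- list(d0 = 4, s0_2 = 1)
  rA <- roast_test(fr, sets, prior, rotation_config(B = 2000, seed = 1))
  rB <- roast_test(fr, sets, prior, rotation_config(B = 4000, seed = 2))
  for (i in seq_len(nrow(rA))) {
    p <- max(rA$p[i], 1 / 2001)
    se <- 2 * sqrt(p * (1 - p) / 2000)
    expect_lt(abs(rA$p[i] - rB$p[i]), 4 * se + 2 / 2001)
  }
})

test_that("rotated score distribution is invariant to a fixed orthogonal transform", {
  # over independent null datasets, p-values computed from the original
  # coordinates and from coordinates passed through one fixed orthogonal
  # map share the same distribution
  set.seed(55)
  prior <- list(d0 = 0, s0_2 = 0)
  Q <- qr.Q(qr(matrix(rnorm(11^2), 11)))  # d + 1 = 11 at n = 6 + 6
  pA <- numeric(60); pB <- numeric(60)
  for (i in 1:60) {
    m <- random_log_matrix(m = 12, n1 = 6, n2 = 6, effect = 0,
                           seed = 5000 + i)
    fr <- make_rotation_frame(m, info_for(m))
    sets <- make_sets(rownames(m$values)[1:6])
    frQ <- fr
    frQ$Y <- fr$Y %*% Q
    pA[i] <- roast_test(fr, sets, prior,
                        rotation_config(B = 99, seed = i))$p
    pB[i] <- roast_test(frQ, sets, prior,
                        rotation_config(B = 99, seed = 1000 + i))$p
  }
  expect_gt(suppressWarnings(ks.test(pA, pB))$p.value, 0.01)
})
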