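test_that("Bray-Curtis matches hand arithmetic and flags empty samples", {
  tab <- cbind(s1 = c(1L, 2L, 0L), s2 = c(0L, 2L, 1L), s3 = c(1L, 2L, 0L),
               s4 = c(5L, 0L, 0L), s5 = c(0L, 0L, 9L))
  d <- bray_curtis(tab)
  expect_equal(d["s1", "s2"], 1 / 3)            # 1 - 2*2/6
  expect_equal(d["s1", "s3"], 0)                # identical samples
  expect_equal(d["s4", "s5"], 1)                # disjoint supports
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_error(bray_curtis(cbind(s1 = c(1L, 0L), s2 = c(0L, 0L))),
               "all-zero")
})

test_that("NMDS embeds planar distances with near-zero stress, deterministically", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4, 5, 5, 1, 3, 4, 1), ncol = 2,
                byrow = TRUE)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:6), sprintf("s%d", 1:6))
  o1 <- nmds_ordinate(d, seed = 12)
  expect_lt(o1$stress, 0.01)
  o2 <- nmds_ordinate(d, seed = 12)
  expect_identical(o1$points, o2$points)

  # rank-preserving transform leaves the stress unchanged
  o3 <- nmds_ordinate(d^2, seed = 12)
  expect_equal(o3$stress, o1$stress, tolerance = 1e-3)
})

test_that("Procrustes M2 is similarity-invariant, symmetric, and permutation-tested", {
  set.seed(77)
  X <- matrix(rnorm(40), ncol = 2)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- 3 * X %*% R + matrix(c(10, -4), nrow(X), 2, byrow = TRUE)
  fit <- procrustes_fit(X, Y, permutations = 199, seed = 1)
  expect_lte(fit$M2, 1e-12)
  expect_true(fit$p > 0 && fit$p <= 1)
  # the aligned target should coincide with the scaled reference
  expect_equal(fit$Yrot, fit$X, tolerance = 1e-9)

  Z <- matrix(rnorm(40), ncol = 2)
  expect_equal(procrustes_fit(X, Z, permutations = 0, seed = 1)$M2,
               procrustes_fit(Z, X, permutations = 0, seed = 1)$M2,
               tolerance = 1e-12)

  rnd <- procrustes_fit(X, Z, permutations = 199, seed = 2)
  expect_gt(rnd$M2, 0.5)
  expect_gt(rnd$p, 0.05)
})

test_that("Procrustes agrees with an independent implementation", {
  set.seed(55)
  for (i in 1:5) {
    X <- matrix(rnorm(30), ncol = 2)
    Y <- matrix(rnorm(30), ncol = 2)
    ours <- procrustes_fit(X, Y, permutations = 0)
    ref <- vegan::procrustes(X, Y, symmetric = TRUE)
    expect_equal(ours$M2, ref$ss, tolerance = 1e-9)
  }
})

test_that("medoid is the brute-force argmin of summed distances", {
  collinear <- cbind(c(0, 1, 10), 0)
  expect_equal(medoid(collinear), 2L)           # sums are 11, 10, 19
  expect_equal(medoid(matrix(c(3, 4), 1)), 1L)
  set.seed(31)
  for (i in 1:25) {
    pts <- matrix(rnorm(2 * sample(3:40, 1)), ncol = 2)
    expect_equal(medoid(pts), brute_medoid(pts))
  }
  # cross-check against PAM with k = 1
  pts <- matrix(rnorm(60), ncol = 2)
  expect_equal(unname(medoid(pts)),
               unname(cluster::pam(pts, k = 1, do.swap = FALSE)$id.med))
})

test_that("delta_e is the signed distance change toward the medoid", {
  expect_equal(delta_e(c(0, 0), a = c(0, 1), b = c(3, 4)), -4)
  expect_equal(delta_e(c(1, 1), a = c(2, 2), b = c(2, 2)), 0)
  set.seed(4)
  m <- rnorm(2); a <- rnorm(2); b <- rnorm(2)
  expect_equal(delta_e(m, a, b), -delta_e(m, b, a))
})

test_that("mean effectiveness is the difference of group means, antisymmetric", {
  expect_equal(mean_effectiveness(c(-4, -2), c(0, 0)), -3)
  expect_equal(mean_effectiveness(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(5)
  g1 <- rnorm(7); g2 <- rnorm(9)
  expect_equal(mean_effectiveness(g1, g2), -mean_effectiveness(g2, g1))
})

test_that("the one-sample effectiveness test matches the t distribution", {
  expect_equal(test_delta_e(c(0, 0, 0, 0)), 1)
  expect_warning(p0 <- test_delta_e(c(2, 2, 2)), "zero-variance")
  expect_equal(p0, 0)

  dE <- c(-1, -1.1, -0.9, -1.0, -1.05)
  expect_lt(test_delta_e(dE), 0.001)
  # literal t statistic: p = 2 * P(T_{n-1} > |mean/(sd/sqrt(n))|)
  tstat <- mean(dE) / (sd(dE) / sqrt(length(dE)))
  expect_equal(test_delta_e(dE), 2 * pt(-abs(tstat), length(dE) - 1))

  set.seed(10)
  for (i in 1:10) {
    v <- rnorm(sample(3:20, 1))
    expect_equal(test_delta_e(v), t.test(v)$p.value)
  }
})

test_that("the pairwise matrix is antisymmetric with calibrated stars", {
  set.seed(40)
  g <- list(a = rnorm(30, -1, 0.1), b = rnorm(30, 0, 0.1),
            c = rnorm(30, 0, 0.1))
  m <- pairwise_matrix(g)
  expect_equal(m$E, -t(m$E))
  expect_equal(m$E["a", "b"], -1, tolerance = 0.1)
  expect_equal(m$stars["a", "b"], "***")
  expect_equal(m$p, t(m$p))

  same <- list(x = c(1, 2, 3), y = c(1, 2, 3))
  ms <- pairwise_matrix(same)
  expect_equal(ms$E["x", "y"], 0)
  expect_equal(ms$stars["x", "y"], "")

  expect_warning(pairwise_matrix(list(a = rnorm(5), b = rnorm(5),
                                      tiny = c(1, 2))), "excluding")
})

test_that("length-effectiveness correlation detects a monotone relation", {
  lengths <- c(g1 = 400, g2 = 450, g3 = 520, g4 = 700)
  # build delta_e vectors whose group means fall with window length
  set.seed(50)
  groups <- lapply(lengths, function(L)
    rnorm(10, mean = -(L - 400) / 100, sd = 0.05))
  pm <- pairwise_matrix(groups)
  lc <- length_effect_correlation(lengths, pm)
  expect_lt(lc$rho, 0)
  expect_equal(nrow(lc$pairs), 6L)

  flat <- pairwise_matrix(list(g1 = c(1, 2, 3), g2 = c(1, 2, 3),
                               g3 = c(1, 2, 3)))
  expect_error(length_effect_correlation(c(g1 = 1, g2 = 2, g3 = 3), flat),
               "constant")
})

test_that("merging clusters yields negative delta_e through the pipeline", {
  set.seed(60)
  # pre: two separated clusters; post: the second collapses onto the first
  # (a batch effect removed) -- samples should converge toward the medoid
  A <- matrix(rnorm(40, sd = 1), ncol = 2)
  B <- matrix(rnorm(40, sd = 1), ncol = 2)
  B[, 1] <- B[, 1] + 8
  pre <- rbind(A, B)
  post <- rbind(A + matrix(rnorm(40, sd = 0.05), ncol = 2),
                matrix(rnorm(40, sd = 1), ncol = 2))
  fit <- procrustes_fit(pre, post, permutations = 99, seed = 3)
  m <- fit$X[medoid(fit$X), ]
  dE <- vapply(seq_len(nrow(pre)), function(i)
    delta_e(m, a = fit$Yrot[i, ], b = fit$X[i, ]), numeric(1))
  expect_lt(mean(dE), 0)
  expect_lt(test_delta_e(dE), 0.05)
  expect_gt(mean(dE < 0), 0.6)
})

test_that("evaluate_correction on an unchanged community is a near-null", {
  # smooth gradient community: low-stress, stable ordination
  mu <- seq(1, 12, length.out = 30)
  tab <- outer(mu, 1:12, function(m, i) as.integer(
    round(500 * exp(-((i - m) / 3)^2)) + 1L))
  dimnames(tab) <- list(sprintf("asv_%d", 1:30), sprintf("s%d", 1:12))
  ev <- suppressWarnings(
    evaluate_correction(tab, tab, permutations = 99, seed = 9))
  expect_lt(ev$procrustes$M2, 0.05)
  expect_lt(abs(mean(ev$delta_e)), 0.05)
  expect_identical(names(ev$delta_e), colnames(tab))
})
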