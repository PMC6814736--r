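test_that("pooled_within_group_variance matches hand-computed sums", {
  # 1 feature, groups {0,2} and {1,3}: SS = 4, df = 2 -> variance 2
  x <- matrix(c(0, 2, 1, 3), 1, 4)
  out <- pooled_within_group_variance(x, c("a", "a", "b", "b"))
  expect_equal(out$variance, 2)
  expect_equal(out$df, 2L)

  # all samples on their centroid -> zero
  x0 <- matrix(c(1, 1, 5, 5), 2, 6)
  expect_equal(pooled_within_group_variance(
    x0, rep(c("a", "b"), 3))$variance, 0)

  # one group: scatter about the grand centroid with df = N - 1
  set.seed(9)
  y <- matrix(rnorm(3 * 8), 3, 8)
  one <- pooled_within_group_variance(y, rep("g", 8))
  expect_equal(one$variance,
               sum(sweep(y, 1, rowMeans(y))^2) / 7, tolerance = 1e-12)

  # reduces to the textbook within-group mean square with one feature
  x1 <- matrix(rnorm(12), 1, 12)
  g <- rep(letters[1:3], 4)
  fit <- stats::anova(stats::lm(as.vector(x1) ~ g))
  expect_equal(pooled_within_group_variance(x1, g)$variance,
               fit["Residuals", "Mean Sq"], tolerance = 1e-10)

  expect_error(pooled_within_group_variance(y, letters[1:8]),
               "degrees of freedom")
})

test_that("pooled variance agrees with the brute-force double loop", {
  set.seed(10)
  for (i in 1:4) {
    x <- matrix(rnorm(6 * 20), 6, 20)
    g <- sample(letters[1:4], 20, replace = TRUE)
    fast <- pooled_within_group_variance(x, g)
    slow <- pool_brute(x, g)
    expect_equal(fast$variance, slow$variance, tolerance = 1e-12)
    expect_equal(fast$df, slow$df)
  }
})

test_that("species_mixing_test orientation, limits and invariances", {
  set.seed(12)
  x <- matrix(rnorm(5 * 24), 5, 24)
  type <- rep(c("t1", "t2", "t3"), 8)
  ds <- rep(c("d1", "d2"), 12)

  # identical partitions give F = 1 exactly
  same <- species_mixing_test(x, type, type)
  expect_equal(same$F, 1)

  # cell types collapsed to points: F diverges, p underflows to 0
  xc <- matrix(0, 5, 24)
  for (k in 1:3) xc[, type == paste0("t", k)] <- k
  lim <- species_mixing_test(xc, type, ds)
  expect_equal(lim$F, Inf)
  expect_equal(lim$p_value, 0)

  res <- species_mixing_test(x, type, ds)
  expect_equal(res$df1, 24L - 3L)
  expect_equal(res$df2, 24L - 2L)
  expect_equal(res$F, res$V_within_dataset / res$V_within_celltype)
  expect_equal(res$p_value,
               pf(res$F, res$df1, res$df2, lower.tail = FALSE))

  # invariant under orthogonal rotation and constant shifts
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  rot <- species_mixing_test(q %*% x, type, ds)
  expect_equal(rot$F, res$F, tolerance = 1e-10)
  shf <- species_mixing_test(x + 3, type, ds)
  expect_equal(shf$F, res$F, tolerance = 1e-10)

  # JSON serialization carries all fields
  j <- jsonlite::fromJSON(ftest_to_json(res))
  expect_equal(j$F, res$F)
  expect_equal(j$df1, res$df1)
  expect_equal(j$N, 24L)
})

test_that("classical_mds recovers Euclidean configurations exactly", {
  # three collinear, equally spaced points
  x <- matrix(c(0, 1, 2), 1, 3,
              dimnames = list("f", c("p1", "p2", "p3")))
  y <- classical_mds(x, dims = 1)
  expect_equal(as.matrix(dist(y)), as.matrix(dist(t(x))),
               tolerance = 1e-10, ignore_attr = TRUE)

  # rank-3 configuration embedded in 10 features: exact recovery at dims 3
  set.seed(14)
  pts <- matrix(rnorm(12 * 3), 12, 3)
  emb <- t(pts %*% matrix(rnorm(3 * 10), 3, 10))
  colnames(emb) <- sprintf("s%02d", 1:12)
  y3 <- classical_mds(emb, dims = 3)
  expect_equal(as.matrix(dist(y3)), as.matrix(dist(t(emb))),
               tolerance = 1e-8, ignore_attr = TRUE)

  # independent oracle: stats::cmdscale, compared up to per-axis sign
  y_or <- stats::cmdscale(dist(t(emb)), k = 3)
  for (k in 1:3)
    expect_equal(abs(y3[, k]), abs(y_or[, k]), tolerance = 1e-8,
                 ignore_attr = TRUE)

  # deterministic sign: largest-magnitude loading positive
  expect_true(all(apply(y3, 2, function(col) col[which.max(abs(col))] > 0)))
  expect_error(classical_mds(emb, dims = 12), "samples")
  expect_error(classical_mds(emb, dims = 8), "positive eigenvalues")
})

test_that("adjusted_rand_index and dendrogram_split_purity behave", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)

  set.seed(15)
  blob <- cbind(matrix(rnorm(3 * 10, 0), 3, 10),
                matrix(rnorm(3 * 10, 8), 3, 10))
  colnames(blob) <- sprintf("s%02d", 1:20)
  lab <- rep(c("x", "y"), each = 10)
  noise <- sample(rep(c("u", "v"), 10))
  out <- dendrogram_split_purity(blob, lab, noise)
  expect_equal(out$winner, "a")
  expect_equal(out$ari_a, 1)

  tie <- dendrogram_split_purity(blob, lab, lab)
  expect_equal(tie$winner, "tie")
  expect_error(dendrogram_split_purity(blob[, 1, drop = FALSE], "a", "a"),
               ">= 2")
})
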