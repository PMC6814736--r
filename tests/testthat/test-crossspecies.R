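make_bpa <- function(rows, cols, seed = 1, prefix = "c") {
  set.seed(seed)
  nes <- matrix(rnorm(length(rows) * cols), length(rows), cols,
                dimnames = list(rows, sprintf("%s%d", prefix, seq_len(cols))))
  bpa_matrix(nes)
}

test_that("merge_bpa intersects set names and never rescales", {
  m1 <- make_bpa(c("A", "B", "C"), 4, seed = 1, prefix = "x")
  m2 <- make_bpa(c("B", "C", "D"), 3, seed = 2, prefix = "y")
  mg <- merge_bpa(list(m1, m2), dataset_labels = c("d1", "d2"))
  expect_equal(rownames(mg$nes), c("B", "C"))
  # bit-identical pass-through
  expect_identical(unname(mg$nes[, 1:4]), unname(m1$nes[c("B", "C"), ]))
  expect_identical(unname(mg$nes[, 5:7]), unname(m2$nes[c("B", "C"), ]))
  expect_equal(mg$annotations$dataset, rep(c("d1", "d2"), c(4, 3)))

  # self-merge duplicates columns, values identical
  sm <- merge_bpa(list(m1, m1))
  expect_equal(ncol(sm$nes), 8L)
  expect_identical(unname(sm$nes[, 1:4]), unname(sm$nes[, 5:8]))

  # disjoint set names: error reporting overlaps
  m3 <- make_bpa(c("E", "F"), 2, seed = 3)
  expect_error(merge_bpa(list(m1, m3)), "overlap")
  expect_error(merge_bpa(list(m1)), ">= 2")
})

test_that("merge_bpa is associative on the shared-row subspace", {
  m1 <- make_bpa(c("A", "B", "C", "D"), 3, seed = 4, prefix = "x")
  m2 <- make_bpa(c("B", "C", "D", "E"), 3, seed = 5, prefix = "y")
  m3 <- make_bpa(c("C", "D", "E", "F"), 3, seed = 6, prefix = "z")
  left <- merge_bpa(list(merge_bpa(list(m1, m2)), m3))
  flat <- merge_bpa(list(m1, m2, m3))
  expect_equal(rownames(left$nes), rownames(flat$nes))
  expect_identical(unname(left$nes), unname(flat$nes))
})

test_that("collapse_orthologs renames, drops and averages collisions", {
  v <- matrix(c(2, 4, 6, 1, 3, 5), 3, 2,
              dimnames = list(c("gA1", "gA2", "gA3"), c("c1", "c2")))

  # identity mapping is the identity transform
  idt <- collapse_orthologs(v, ortholog_table(rownames(v), rownames(v)))
  expect_equal(idt$values, v)

  # two source genes -> one target: averaged (2 and 4 -> 3)
  tab <- ortholog_table(c("gA1", "gA2", "gA3"), c("m1", "m1", "m2"))
  suppressMessages(out <- collapse_orthologs(v, tab))
  expect_equal(out$values["m1", ], c(c1 = 3, c2 = 2))
  expect_equal(out$values["m2", ], c(c1 = 6, c2 = 5))

  # unmapped genes are dropped and counted in provenance
  tab2 <- ortholog_table(c("gA1", "gA2"), c("m1", "m2"))
  out2 <- collapse_orthologs(v, tab2)
  expect_equal(rownames(out2$values), c("m1", "m2"))
  rec <- out2$provenance[[length(out2$provenance)]]
  expect_equal(rec$dropped, 1L)

  # reverse direction
  rev <- collapse_orthologs(out2, tab2, direction = "b_to_a")
  expect_equal(rev$values, v[1:2, ])

  expect_error(collapse_orthologs(v, ortholog_table("qq", "ww")),
               "no gene")
})

test_that("dtw_align: identity, hand example, brute-force agreement", {
  set.seed(7)
  m <- matrix(rnorm(15), 5, 3)
  r <- dtw_align(m, m)
  expect_equal(r$cost, 0)
  expect_equal(unname(r$path), cbind(1:5, 1:5))

  # scalar sequences, absolute distance: minimum over monotone paths is 1
  r2 <- dtw_align(c(0, 1, 2), c(0, 2), metric = "manhattan")
  expect_equal(r2$cost, 1)
  expect_valid_dtw_path(r2, 3, 2)

  # random multivariate instance vs exhaustive enumeration
  a <- matrix(rnorm(5 * 2), 5, 2)
  b <- matrix(rnorm(4 * 2), 4, 2)
  r3 <- dtw_align(a, b)
  expect_equal(r3$cost, dtw_brute_cost(a, b), tolerance = 1e-12)
  expect_valid_dtw_path(r3, 5, 4)

  expect_error(dtw_align(matrix(1, 2, 2), matrix(1, 2, 3)),
               "feature mismatch")
})

test_that("dtw cost is symmetric and bounded below", {
  set.seed(8)
  for (i in 1:5) {
    a <- matrix(rnorm(4 * 3), 4, 3)
    b <- matrix(rnorm(6 * 3), 6, 3)
    cab <- dtw_align(a, b)$cost
    expect_equal(cab, dtw_align(b, a)$cost, tolerance = 1e-12)
    # every element of one sequence must be visited at least once
    dmin <- min(as.matrix(stats::dist(rbind(a, b)))[1:4, 5:10])
    expect_gte(cab, dmin - 1e-12)
  }
})

test_that("stage_profiles aggregates cells by stage in order", {
  nes <- matrix(c(1, 2, 3, 5, 10, 20), 1, 6,
                dimnames = list("S", sprintf("c%d", 1:6)))
  b <- bpa_matrix(nes)
  stages <- c("s1", "s1", "s2", "s2", "s3", "s3")
  prof <- stage_profiles(b, stages)
  expect_equal(unname(prof[, 1]), c(1.5, 4, 15))
  expect_equal(rownames(prof), c("s1", "s2", "s3"))
  expect_equal(unname(stage_profiles(b, stages, fun = "median")[, 1]),
               c(1.5, 4, 15))
  expect_error(stage_profiles(b, stages, stage_order = c("s1", "s9")),
               "s9")
})
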