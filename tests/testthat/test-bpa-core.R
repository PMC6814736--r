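test_that("signature_from_expression: ranks, ties, monotone invariance", {
  # N = 3: ranks (3,1,2) -> scaled (0.75, 0.25, 0.50) -> normal quantiles
  sig <- signature_from_expression(c(a = 5, b = 1, c = 3))
  expect_equal(sig$gene_ids, c("a", "b", "c"))
  expect_equal(sig$z, qnorm(c(0.75, 0.25, 0.50)), tolerance = 1e-12)
  expect_equal(sum(sig$z), 0, tolerance = 1e-12)

  # tied pair: averaged ranks land on the median quantile
  expect_warning(tie <- signature_from_expression(c(7, 7)), "flat")
  expect_equal(tie$z, c(0, 0))

  # rank invariance under a strictly monotone transform
  set.seed(5)
  x <- rnorm(100, 3, 1)
  s1 <- signature_from_expression(x)
  s2 <- signature_from_expression(exp(x) + 2)
  expect_equal(s1$z, s2$z)

  expect_error(signature_from_expression(3), ">= 2 genes")
  expect_error(signature_from_expression(c(1, NA)), "finite")
})

test_that("area_nes matches the quantile-function oracle", {
  ids <- letters[1:9]
  sig <- signature_from_expression(setNames(1:9, ids))  # tie-free

  # the whole signature: quantiles sum to zero by symmetry
  expect_equal(area_nes(sig, gene_set("all", ids)), 0, tolerance = 1e-12)

  # single top-ranked gene: NES = qnorm(9/10)
  expect_equal(area_nes(sig, gene_set("top1", "i")), qnorm(0.9),
               tolerance = 1e-12)

  # top 4 genes: sum of tabulated quantiles / sqrt(4)
  expect_equal(area_nes(sig, gene_set("top4", c("i", "h", "g", "f"))),
               sum(qnorm(c(0.9, 0.8, 0.7, 0.6))) / 2, tolerance = 1e-12)

  expect_error(area_nes(sig, gene_set("bad", c("i", "nope"))),
               "absent from the signature")
})

test_that("bpa_transform composes per-cell signatures with set scoring", {
  set.seed(11)
  v <- matrix(runif(200 * 6, 0, 10), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("c%d", 1:6)))
  coll <- gene_set_collection(lapply(1:5, function(i)
    gene_set(sprintf("S%d", i), sprintf("g%03d", ((i - 1) * 40 + 1):(i * 40)))))

  b <- bpa_transform(v, coll)
  expect_equal(dim(b$nes), c(5L, 6L))

  # agrees with the scalar path cell by cell, set by set
  for (j in c(1, 4)) {
    sig <- signature_from_expression(v[, j])
    for (s in names(coll$sets))
      expect_equal(b$nes[s, j], area_nes(sig, coll$sets[[s]]),
                   tolerance = 1e-12)
  }

  # a set spanning the full universe of a tie-free cell scores 0
  whole <- gene_set_collection(list(gene_set("W", rownames(v))))
  expect_equal(unname(bpa_transform(v[, 1:2], whole)$nes[1, ]), c(0, 0),
               tolerance = 1e-12)

  # per-cell contract: duplicating a column duplicates its NES column
  v2 <- cbind(v, dup = v[, 3])
  b2 <- bpa_transform(v2, coll)
  expect_identical(unname(b2$nes[, "dup"]), unname(b2$nes[, "c3"]))

  # rank invariance propagates through the transform
  b3 <- bpa_transform(v^3, coll)
  expect_equal(b3$nes, b$nes)

  # no surviving set: error reports the overlap counts
  expect_error(bpa_transform(v, coll, min_overlap = 41), "overlaps")
})

test_that("NES is approximately standard normal for random sets", {
  set.seed(23)
  n_genes <- 1500
  sig <- signature_from_expression(rnorm(n_genes),
                                   gene_ids = sprintf("g%d", 1:n_genes))
  nes <- replicate(400, {
    gs <- gene_set("r", sprintf("g%d", sample.int(n_genes, 30)))
    area_nes(sig, gs)
  })
  expect_lt(abs(mean(nes)), 0.1)
  expect_gt(sd(nes), 0.9)
  expect_lt(sd(nes), 1.1)
})

test_that("select_by_sd keeps the most variable sets deterministically", {
  nes <- rbind(flatrow = rep(1, 6),
               vary = c(0, 2, 0, 2, 0, 2))
  colnames(nes) <- sprintf("c%d", 1:6)
  b <- bpa_matrix(nes)
  expect_equal(rownames(select_by_sd(b, 1)$nes), "vary")
  expect_setequal(rownames(select_by_sd(b, 2)$nes), rownames(nes))

  # ties broken by set name, lexicographically
  nes2 <- rbind(zz = c(0, 1, 0, 1), aa = c(1, 0, 1, 0),
                mid = c(0, 0.1, 0, 0.1))
  colnames(nes2) <- sprintf("c%d", 1:4)
  out <- select_by_sd(bpa_matrix(nes2), 2)
  expect_equal(rownames(out$nes), c("aa", "zz"))
  expect_error(select_by_sd(bpa_matrix(nes2), 4), "top_k")
})

test_that("expression containers validate and round-trip via TSV and MTX", {
  set.seed(3)
  v <- matrix(abs(rnorm(30)), 5, 6,
              dimnames = list(sprintf("g%d", 1:5), sprintf("c%d", 1:6)))
  em <- expression_matrix(v, log_base_note = "log2(TPM+1)")
  expect_equal(dim(em), c(5L, 6L))
  expect_error(expression_matrix(v - 10), ">= 0")
  expect_error(expression_matrix(unname(v)), "rownames")

  p <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(em, p)
  back <- read_expression_tsv(p)
  expect_equal(back$values, v, tolerance = 1e-9)

  # MTX triplet
  d <- withr::local_tempdir()
  Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), file.path(d, "m.mtx"))
  writeLines(rownames(v), file.path(d, "features.tsv"))
  writeLines(colnames(v), file.path(d, "barcodes.tsv"))
  mm <- read_expression_mtx(file.path(d, "m.mtx"),
                            file.path(d, "features.tsv"),
                            file.path(d, "barcodes.tsv"))
  expect_equal(mm$values, v, tolerance = 1e-12)
})
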