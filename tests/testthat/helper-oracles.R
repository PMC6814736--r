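# Shared fixtures and *independent* oracles used by unit and acceptance
# tests. Oracles deliberately avoid the code paths they check: permutation
# sampling instead of the analytic NES, explicit double loops instead of
# vectorized pooled variances, exhaustive path enumeration instead of the
# DTW dynamic program.

small_spec <- function(...) {
  do.call(fixture_spec,
          utils::modifyList(list(n_cell_types = 2L, cells_per_type = 12L,
                                 n_genes = 300L, n_sets = 6L,
                                 genes_per_set = 40L, seed = 42L),
                            list(...)))
}

# Permutation z-score for the enrichment of `set_idx` in quantile vector z:
# null = sums over random same-size gene draws.
perm_nes_oracle <- function(z, set_idx, n_perm = 1e4) {
  n <- length(set_idx)
  obs <- sum(z[set_idx]) / sqrt(n)
  null <- vapply(seq_len(n_perm), function(i)
    sum(z[sample.int(length(z), n)]) / sqrt(n), numeric(1))
  (obs - mean(null)) / sd(null)
}

# Exhaustive DTW: enumerate every monotone path with steps
# {(1,0),(0,1),(1,1)} and return the minimum total cost.
dtw_brute_cost <- function(a, b, metric = "euclidean") {
  a <- if (is.matrix(a)) a else matrix(a, ncol = 1)
  b <- if (is.matrix(b)) b else matrix(b, ncol = 1)
  d <- function(i, j) {
    diff <- a[i, ] - b[j, ]
    if (metric == "euclidean") sqrt(sum(diff^2)) else sum(abs(diff))
  }
  na <- nrow(a); nb <- nrow(b)
  rec <- function(i, j) {
    if (i == na && j == nb) return(d(i, j))
    best <- Inf
    if (i < na && j < nb) best <- min(best, rec(i + 1, j + 1))
    if (i < na) best <- min(best, rec(i + 1, j))
    if (j < nb) best <- min(best, rec(i, j + 1))
    d(i, j) + best
  }
  rec(1, 1)
}

# Textbook double-loop pooled within-group variance.
pool_brute <- function(x, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  ss <- 0
  for (g in groups) {
    idx <- which(labels == g)
    centroid <- rowMeans(x[, idx, drop = FALSE])
    for (s in idx)
      for (f in seq_len(nrow(x)))
        ss <- ss + (x[f, s] - centroid[f])^2
  }
  list(variance = ss / (ncol(x) - length(groups)),
       df = ncol(x) - length(groups))
}

# Validity check for a DTW path (1-based index pairs).
expect_valid_dtw_path <- function(res, na, nb) {
  expect_equal(unname(res$path[1, ]), c(1L, 1L))
  expect_equal(unname(res$path[nrow(res$path), ]), c(na, nb))
  steps <- diff(res$path)
  expect_true(all(steps >= 0 & steps <= 1))
  expect_true(all(rowSums(steps) >= 1))
}

write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Mean correlation between (or within) column groups of a matrix.
mean_group_cor <- function(m, idx1, idx2) {
  cc <- cor(m[, idx1, drop = FALSE], m[, idx2, drop = FALSE])
  if (identical(idx1, idx2)) mean(cc[upper.tri(cc)]) else mean(cc)
}
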