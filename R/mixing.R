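#' Pooled within-group variance of a multivariate sample
#'
#' The dispersion used by the species-mixing test: the sum over samples of
#' squared Euclidean distance to their own group centroid, divided by
#' N - M degrees of freedom (N samples, M groups). With a single feature
#' this is exactly the textbook within-group mean square of one-way
#' analysis of variance.
#'
#' @param x Features x samples numeric matrix.
#' @param labels Group label per sample (any atomic type).
#' @return List with `variance`, `df` (= N - M), `ss` (raw sum of
#'   squares), and `n_groups`.
#' @export
pooled_within_group_variance <- function(x, labels) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (length(labels) != n) stopf("one label per sample required")
  if (n < 2L) stopf("need >= 2 samples")
  labels <- as.character(labels)
  m <- length(unique(labels))
  if (n - m < 1L)
    stopf("zero degrees of freedom: %d samples in %d groups", n, m)
  xt <- t(x)
  centroids <- rowsum(xt, labels)
  centroids <- centroids / as.vector(table(labels)[rownames(centroids)])
  ss <- sum((xt - centroids[labels, , drop = FALSE])^2)
  list(variance = ss / (n - m), df = n - m, ss = ss, n_groups = m)
}

#' Species-mixing variance-ratio test
#'
#' Asks whether, in activity (or expression) space, cells of the same cell
#' type sit closer together than cells of the same dataset/species. Two
#' pooled within-group variances are computed on the same cells: Vt under
#' the cell-type labeling and Vs under the dataset labeling. The statistic
#' is oriented as
#' \deqn{F = V_s / V_t,}
#' so values above 1 mean cell types are tighter than datasets — i.e. the
#' datasets/species mix within cell types. The ratio is referred to an F
#' distribution with (N - Mt, N - Ms) degrees of freedom (one-sided,
#' upper tail). Note this reference distribution is heuristic: both
#' variances are computed from the same cells, so under a null of
#' exchangeable cells the ratio is far more concentrated around 1 than an
#' F variate with these degrees of freedom (p-values are conservative
#' near 0.5, not uniform); treat p as a descriptive index, not a
#' calibrated tail probability.
#'
#' @param x A `bpa_matrix`, or a features x samples matrix.
#' @param cell_type_labels,dataset_labels Label per cell. For a
#'   `bpa_matrix` they default to the `cell_type` / `dataset` annotation
#'   columns.
#' @return Object of class `bpa_ftest` with fields `V_within_celltype`
#'   (Vt), `V_within_dataset` (Vs), `F`, `df1` (N - Mt), `df2` (N - Ms),
#'   `p_value`, `N`, `M_t`, `M_s`, and an `orientation` note.
#' @export
species_mixing_test <- function(x, cell_type_labels = NULL,
                                dataset_labels = NULL) {
  if (inherits(x, "bpa_matrix")) {
    ann <- x$annotations
    if (is.null(cell_type_labels)) cell_type_labels <- ann$cell_type
    if (is.null(dataset_labels)) dataset_labels <- ann$dataset
    x <- x$nes
  }
  if (is.null(cell_type_labels) || is.null(dataset_labels))
    stopf("cell type and dataset labels are required")
  x <- as.matrix(x)
  n <- ncol(x)
  mt <- length(unique(as.character(cell_type_labels)))
  ms <- length(unique(as.character(dataset_labels)))
  if (mt < 2L && ms < 2L)
    stopf("at least one labeling must have >= 2 groups")
  vt <- pooled_within_group_variance(x, cell_type_labels)
  vs <- pooled_within_group_variance(x, dataset_labels)
  f <- if (vt$variance == 0) Inf else vs$variance / vt$variance
  p <- pf(f, df1 = n - mt, df2 = n - ms, lower.tail = FALSE)
  structure(
    list(V_within_celltype = vt$variance, V_within_dataset = vs$variance,
         F = f, df1 = n - mt, df2 = n - ms, p_value = p,
         N = n, M_t = mt, M_s = ms,
         orientation = paste("F = V_within_dataset / V_within_celltype;",
                             "F > 1 means datasets mix within cell types")),
    class = "bpa_ftest")
}

#' @export
print.bpa_ftest <- function(x, ...) {
  cat(sprintf(
    "species-mixing F test: F = %.4g on (%d, %d) df, p = %.3g\n",
    x$F, x$df1, x$df2, x$p_value))
  cat(sprintf("  Vt (within cell type) = %.4g, Vs (within dataset) = %.4g\n",
              x$V_within_celltype, x$V_within_dataset))
  cat(" ", x$orientation, "\n")
  invisible(x)
}

#' Serialize an F-test result to JSON
#' @param x A `bpa_ftest`.
#' @param path Optional output path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
ftest_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "bpa_ftest"))
  obj <- unclass(x)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Deterministic MDS: Euclidean distances between samples, double-centered
#' Gram matrix, top eigenvectors scaled by the square root of their
#' eigenvalues. The per-axis sign ambiguity is resolved by forcing the
#' largest-magnitude loading of each axis positive. Components attached to
#' negative eigenvalues (possible only for non-Euclidean inputs) are
#' dropped with a warning; requesting more dimensions than there are
#' positive eigenvalues is an error.
#'
#' @param x Features x samples matrix.
#' @param dims Number of output dimensions (>= 1, <= samples - 1).
#' @return Samples x dims matrix of coordinates (rownames = sample ids).
#' @export
classical_mds <- function(x, dims = 2L) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (dims < 1L) stopf("dims must be >= 1")
  if (n < dims + 1L) stopf("need >= dims + 1 samples")
  d2 <- as.matrix(dist(t(x)))^2
  b <- -0.5 * (d2 - outer(rowMeans(d2), rep(1, n)) -
                 outer(rep(1, n), colMeans(d2)) + mean(d2))
  e <- eigen(b, symmetric = TRUE)
  tol <- max(abs(e$values)) * sqrt(.Machine$double.eps)
  if (any(e$values < -tol))
    warnf("dropping %d negative-eigenvalue component(s)",
          sum(e$values < -tol))
  npos <- sum(e$values > tol)
  if (dims > npos)
    stopf("dims = %d exceeds number of positive eigenvalues (%d)",
          dims, npos)
  y <- e$vectors[, seq_len(dims), drop = FALSE] *
    rep(sqrt(e$values[seq_len(dims)]), each = n)
  for (k in seq_len(dims))
    if (y[which.max(abs(y[, k])), k] < 0) y[, k] <- -y[, k]
  rownames(y) <- colnames(x)
  colnames(y) <- sprintf("MDS%d", seq_len(dims))
  y
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in [-1, 1]; 1 for identical partitions, ~0 for independent
#'   ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors must have equal length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  npairs <- choose(sum(tab), 2)
  expected <- ai * bj / npairs
  maxidx <- (ai + bj) / 2
  if (maxidx == expected) return(ifelse(nij == expected, 1, 0))
  (nij - expected) / (maxidx - expected)
}

#' Which labeling does the top dendrogram split follow?
#'
#' Average-linkage hierarchical clustering on Euclidean distances, cut at
#' the root into two branches; the two-branch partition is compared by
#' adjusted Rand index to two candidate labelings (e.g. cell type vs
#' species) and the better-matching one is reported.
#'
#' @param x Features x samples matrix (or `bpa_matrix`).
#' @param labels_a,labels_b Candidate labelings, one label per sample.
#' @return List with `winner` (`"a"`, `"b"` or `"tie"`), `ari_a`, `ari_b`
#'   and the two-branch `split` vector.
#' @export
dendrogram_split_purity <- function(x, labels_a, labels_b) {
  if (inherits(x, "bpa_matrix")) x <- x$nes
  x <- as.matrix(x)
  if (ncol(x) < 2L) stopf("need >= 2 samples")
  if (length(labels_a) != ncol(x) || length(labels_b) != ncol(x))
    stopf("one label per sample required")
  hc <- hclust(dist(t(x)), method = "average")
  split <- cutree(hc, k = 2L)
  ari_a <- adjusted_rand_index(split, labels_a)
  ari_b <- adjusted_rand_index(split, labels_b)
  winner <- if (isTRUE(all.equal(ari_a, ari_b))) "tie"
            else if (ari_a > ari_b) "a" else "b"
  list(winner = winner, ari_a = ari_a, ari_b = ari_b, split = split)
}
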