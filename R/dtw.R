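#' Dynamic time warping of two staged profile sequences
#'
#' Aligns two ordered sequences of stage profiles (e.g. per-stage mean BPA
#' vectors of two species' developmental timelines) by the classic dynamic
#' program with step set \{(1,0), (0,1), (1,1)\} and no window. The cost of
#' an alignment is the sum of pairwise distances over every cell the path
#' visits; the global minimum and one optimal path are returned, ties
#' broken preferring the diagonal step, then (1,0).
#'
#' @param seq_a,seq_b Numeric matrices (stages in rows, features in
#'   columns) sharing a feature space, or plain numeric vectors (treated
#'   as one-feature sequences).
#' @param metric `"euclidean"` (default) or `"manhattan"` pointwise
#'   distance.
#' @return Object of class `dtw_result`: `cost` (total alignment cost) and
#'   `path`, a two-column matrix of 1-based (a_index, b_index) pairs
#'   running from (1,1) to (nrow(seq_a), nrow(seq_b)).
#' @export
dtw_align <- function(seq_a, seq_b, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  a <- if (is.matrix(seq_a)) seq_a else matrix(seq_a, ncol = 1L)
  b <- if (is.matrix(seq_b)) seq_b else matrix(seq_b, ncol = 1L)
  if (nrow(a) == 0L || nrow(b) == 0L) stopf("sequences must be non-empty")
  if (ncol(a) != ncol(b))
    stopf("feature mismatch: %d vs %d features", ncol(a), ncol(b))
  na <- nrow(a); nb <- nrow(b)
  d <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    diff <- a - matrix(b[j, ], na, ncol(a), byrow = TRUE)
    d[, j] <- switch(metric,
                     euclidean = sqrt(rowSums(diff^2)),
                     manhattan = rowSums(abs(diff)))
  }
  cum <- matrix(Inf, na, nb)
  from <- matrix(0L, na, nb)  # 1 = diag, 2 = (1,0), 3 = (0,1)
  cum[1, 1] <- d[1, 1]
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (i == 1L && j == 1L) next
      cand <- c(if (i > 1L && j > 1L) cum[i - 1L, j - 1L] else Inf,
                if (i > 1L) cum[i - 1L, j] else Inf,
                if (j > 1L) cum[i, j - 1L] else Inf)
      best <- which.min(cand)  # ties -> lowest index: diag, then (1,0)
      cum[i, j] <- d[i, j] + cand[best]
      from[i, j] <- best
    }
  }
  path <- matrix(0L, na + nb, 2L)
  i <- na; j <- nb; k <- 0L
  repeat {
    k <- k + 1L
    path[k, ] <- c(i, j)
    if (i == 1L && j == 1L) break
    step <- from[i, j]
    if (step == 1L) { i <- i - 1L; j <- j - 1L }
    else if (step == 2L) i <- i - 1L
    else j <- j - 1L
  }
  path <- path[k:1, , drop = FALSE]
  colnames(path) <- c("a", "b")
  structure(list(cost = cum[na, nb], path = path, metric = metric),
            class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("dtw_result: cost %.6g, path length %d (%s)\n",
              x$cost, nrow(x$path), x$metric))
  invisible(x)
}

#' Per-stage aggregate profiles from a BPA matrix
#'
#' Convenience aggregation used before [dtw_align()]: cells are grouped by
#' a stage label and each stage is summarized by the mean (or median) NES
#' vector, returned in the order of `stage_order` (default: order of first
#' appearance).
#'
#' @param bpa A `bpa_matrix`.
#' @param stage_labels Stage label per cell.
#' @param stage_order Optional explicit stage ordering.
#' @param fun `"mean"` (default) or `"median"`.
#' @return Stages x sets numeric matrix.
#' @export
stage_profiles <- function(bpa, stage_labels, stage_order = NULL,
                           fun = c("mean", "median")) {
  fun <- match.arg(fun)
  stopifnot(inherits(bpa, "bpa_matrix"))
  if (length(stage_labels) != ncol(bpa$nes))
    stopf("one stage label per cell required")
  if (is.null(stage_order)) stage_order <- unique(as.character(stage_labels))
  f <- if (fun == "mean") rowMeans else function(m) apply(m, 1L, stats::median)
  v <- vapply(stage_order, function(s) {
    idx <- which(as.character(stage_labels) == s)
    if (!length(idx)) stopf("stage '%s' has no cells", s)
    f(bpa$nes[, idx, drop = FALSE])
  }, numeric(nrow(bpa$nes)))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L, dimnames = list(
    rownames(bpa$nes), stage_order))
  prof <- t(v)
  rownames(prof) <- stage_order
  prof
}
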