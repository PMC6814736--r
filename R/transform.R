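#' Rank-quantile signature of one cell
#'
#' The enrichment machinery works on a per-cell *signature*: the cell's
#' genes are ranked by log expression (ascending; ties get the mean of
#' their rank positions, so the large zero block typical of single-cell
#' data forms one averaged tie), ranks are scaled as r/(N+1), and mapped
#' through the standard-normal quantile function. The resulting z values
#' are symmetric about zero and sum to zero in the tie-free case, and any
#' strictly monotone transform of the input leaves them unchanged — the
#' transform depends on expression only through ranks.
#'
#' @param x Numeric vector of log expression for one cell (length >= 2,
#'   finite). Names, if present, become the signature's gene ids.
#' @param gene_ids Optional character vector of gene ids.
#' @return Object of class `rank_signature`: list with `gene_ids` and `z`.
#' @export
signature_from_expression <- function(x, gene_ids = names(x)) {
  if (length(x) < 2L) stopf("signature needs >= 2 genes")
  if (!all(is.finite(x))) stopf("signature values must be finite")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_along(x))
  if (length(gene_ids) != length(x)) stopf("gene_ids length mismatch")
  n <- length(x)
  if (max(x) == min(x))
    warnf("flat signature: all %d values identical, all z set to 0", n)
  z <- qnorm(unname(rank(x, ties.method = "average")) / (n + 1))
  structure(list(gene_ids = gene_ids, z = z), class = "rank_signature")
}

#' Analytic normalized enrichment score of a gene set in one signature
#'
#' The unsigned-gene-set specialization of analytic rank-based enrichment:
#' with uniform weights and all members treated as positively associated,
#' the normalized enrichment score is
#' \deqn{NES = \sum_{i \in S} z_i / \sqrt{n},}
#' the z-score of the mean rank quantile over the n set members. Under a
#' random signature this is approximately standard normal, which is what
#' licenses merging scores across datasets without renormalization.
#'
#' @param sig A `rank_signature`.
#' @param gs A `gene_set` whose genes are all present in the signature
#'   (use [restrict_to_universe()] first); this is a contract, violation
#'   is an error.
#' @return A single numeric NES.
#' @export
area_nes <- function(sig, gs) {
  idx <- match(gs$genes, sig$gene_ids)
  if (anyNA(idx))
    stopf("gene set '%s' has %d gene(s) absent from the signature; %s",
          gs$name, sum(is.na(idx)),
          "restrict the collection to the measured universe first")
  sum(sig$z[idx]) / sqrt(length(idx))
}

#' Construct a BPA (pathway activity) matrix
#'
#' @param nes Numeric sets x cells matrix with dimnames.
#' @param annotations Data frame with one row per cell; must contain a
#'   `cell_id` column covering every column of `nes`. Extra columns
#'   (`cell_type`, `dataset`, `species`) are carried along.
#' @param provenance List of provenance records.
#' @return Object of class `bpa_matrix`.
#' @export
bpa_matrix <- function(nes, annotations = NULL, provenance = list()) {
  nes <- as.matrix(nes)
  if (is.null(rownames(nes)) || is.null(colnames(nes)))
    stopf("NES matrix needs set rownames and cell colnames")
  if (anyDuplicated(rownames(nes))) stopf("duplicate set names")
  if (!all(is.finite(nes))) stopf("NES values must be finite")
  if (is.null(annotations))
    annotations <- data.frame(cell_id = colnames(nes),
                              stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(annotations))
    stopf("annotations need a 'cell_id' column")
  if (!all(colnames(nes) %in% annotations$cell_id))
    stopf("annotations do not cover all cells")
  annotations <- annotations[match(colnames(nes), annotations$cell_id), ,
                             drop = FALSE]
  rownames(annotations) <- NULL
  structure(list(nes = nes, annotations = annotations,
                 provenance = provenance),
            class = "bpa_matrix")
}

#' @export
print.bpa_matrix <- function(x, ...) {
  cat(sprintf("bpa_matrix: %d gene sets x %d cells\n",
              nrow(x$nes), ncol(x$nes)))
  extra <- setdiff(names(x$annotations), "cell_id")
  if (length(extra))
    cat("  annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.bpa_matrix <- function(x) dim(x$nes)

#' BPA transform: expression to pathway-activity z-scores
#'
#' For every cell, builds the rank-quantile signature from that cell's own
#' log expression (single-sample enrichment: no dataset-average signature
#' is subtracted, so a cell's activities do not depend on which other
#' cells happen to be in the matrix) and scores every gene set with
#' [area_nes()]. Cells are processed independently; the result for cell c
#' depends only on column c.
#'
#' @param expr An `expr_matrix` or genes x cells matrix (log scale).
#' @param coll A `gene_set_collection`.
#' @param min_overlap Sets with fewer than this many measured genes are
#'   dropped (see [restrict_to_universe()]).
#' @param annotations Optional per-cell annotation data frame (`cell_id`
#'   plus `cell_type`/`dataset`/`species`).
#' @param relative If `TRUE`, subtract the dataset-average signature from
#'   every cell before ranking (the differential mode deliberately *not*
#'   used by default, because it makes each cell's activities depend on
#'   dataset composition and hurts cross-dataset integration). Off by
#'   default; provided only for comparison experiments.
#' @return A `bpa_matrix` (sets x cells).
#' @export
bpa_transform <- function(expr, coll, min_overlap = 5L, annotations = NULL,
                          relative = FALSE) {
  v <- as_expr_values(expr)
  if (nrow(v) < 2L) stopf("need >= 2 genes")
  restricted <- restrict_to_universe(coll, rownames(v), min_overlap)
  if (length(restricted) == 0L) {
    ov <- vapply(coll$sets, function(s) sum(s$genes %in% rownames(v)),
                 integer(1))
    stopf("no gene set has >= %d genes in the matrix; overlaps: %s",
          min_overlap,
          paste(sprintf("%s=%d", names(ov), ov), collapse = ", "))
  }
  if (relative) v <- sweep(v, 1L, rowMeans(v))
  n <- nrow(v)
  flat <- apply(v, 2L, function(col) max(col) == min(col))
  if (any(flat))
    warnf("%d flat cell(s) (all genes tied): their NES are all 0",
          sum(flat))
  z <- qnorm(apply(v, 2L, rank, ties.method = "average") / (n + 1))
  sizes <- set_sizes(restricted)
  memb <- Matrix::sparseMatrix(
    i = rep.int(seq_along(restricted$sets), sizes),
    j = match(unlist(lapply(restricted$sets, `[[`, "genes"),
                     use.names = FALSE), rownames(v)),
    x = 1, dims = c(length(restricted), n))
  nes <- as.matrix(memb %*% z) / sqrt(sizes)
  dimnames(nes) <- list(names(restricted$sets), colnames(v))
  bpa_matrix(
    nes, annotations = annotations,
    provenance = prov_add(
      restricted$provenance, "bpa_transform",
      n_genes = n, n_cells = ncol(v), n_sets = length(restricted),
      rank_scaling = "r/(N+1), ties averaged", relative = relative))
}

#' Select the most variable gene sets
#'
#' The standard deviation of a set's NES across cells reflects whether the
#' set encodes information that differs between the cells at hand, so it
#' can be used to pick which processes to analyze in a given dataset.
#' Retains the `top_k` sets by sample SD; ties are broken by set-name
#' lexicographic order so selection is deterministic.
#'
#' @param bpa A `bpa_matrix`.
#' @param top_k Number of sets to keep (`1 <= top_k <= nrow`).
#' @return A `bpa_matrix` with rows ordered by decreasing SD.
#' @export
select_by_sd <- function(bpa, top_k) {
  stopifnot(inherits(bpa, "bpa_matrix"))
  if (top_k < 1L || top_k > nrow(bpa$nes))
    stopf("top_k must be in [1, %d]", nrow(bpa$nes))
  sds <- apply(bpa$nes, 1L, sd)
  # C-locale, case-sensitive name order for reproducible tie-breaks
  ord <- order(-sds, xtfrm(factor(rownames(bpa$nes),
                                  levels = sort(rownames(bpa$nes),
                                                method = "radix"))))
  keep <- ord[seq_len(top_k)]
  bpa_matrix(bpa$nes[keep, , drop = FALSE], annotations = bpa$annotations,
             provenance = prov_add(bpa$provenance, "select_by_sd",
                                   top_k = top_k))
}

#' Write / read a BPA matrix as TSV (+ JSON provenance sidecar)
#'
#' @param bpa A `bpa_matrix`.
#' @param path TSV path (sets in rows, cells in columns); provenance goes
#'   to `<path>.prov.json` and annotations to `<path>.annotations.tsv`.
#' @return `path`, invisibly.
#' @export
write_bpa_tsv <- function(bpa, path) {
  write.table(data.frame(set = rownames(bpa$nes), bpa$nes,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bpa$annotations, paste0(path, ".annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bpa$provenance, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_bpa_tsv
#' @param dataset Dataset label used when no annotation sidecar exists.
#' @return `read_bpa_tsv`: a `bpa_matrix`.
#' @export
read_bpa_tsv <- function(path, dataset = basename(path)) {
  if (!file.exists(path)) stopf("BPA file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, row.names = 1,
                   check.names = FALSE)
  ann_path <- paste0(path, ".annotations.tsv")
  ann <- if (file.exists(ann_path)) {
    read.delim(ann_path, sep = "\t", header = TRUE, check.names = FALSE,
               colClasses = "character")
  } else {
    data.frame(cell_id = colnames(df), dataset = dataset,
               stringsAsFactors = FALSE)
  }
  bpa_matrix(as.matrix(df), annotations = ann,
             provenance = prov_add(list(), "read_bpa_tsv", path = path))
}
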