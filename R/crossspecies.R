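#' Merge BPA matrices across datasets or species
#'
#' Because NES values are (approximately) standard-normal z-scores, BPA
#' matrices from different datasets — or different species, provided the
#' collections share gene-set *names* — can be concatenated directly with
#' no rescaling. Rows are the intersection of set names, in the first
#' matrix's order; a union would instead create structurally missing
#' blocks that break downstream distance computations. NES values are
#' copied bit-for-bit.
#'
#' @param matrices List of >= 2 `bpa_matrix` objects.
#' @param dataset_labels Optional character vector (one per matrix) used
#'   to fill/override the `dataset` annotation column.
#' @return A merged `bpa_matrix`. Cell ids colliding across matrices are
#'   disambiguated with a `#<k>` suffix (original ids kept in the
#'   `cell_id_original` annotation column).
#' @export
merge_bpa <- function(matrices, dataset_labels = NULL) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stopf("need a list of >= 2 bpa_matrix objects")
  stopifnot(all(vapply(matrices, inherits, logical(1), "bpa_matrix")))
  if (is.null(dataset_labels))
    dataset_labels <- sprintf("dataset%d", seq_along(matrices))
  rows <- lapply(matrices, function(m) rownames(m$nes))
  shared <- Reduce(intersect, rows)
  shared <- rows[[1]][rows[[1]] %in% shared]  # first matrix's order
  if (length(shared) == 0L) {
    k <- length(matrices)
    ov <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
      length(intersect(rows[[i]], rows[[j]]))))
    stopf("no gene-set name shared by all matrices; pairwise overlaps: %s",
          paste(sprintf("(%d,%d)=%d", row(ov)[upper.tri(ov)],
                        col(ov)[upper.tri(ov)], ov[upper.tri(ov)]),
                collapse = " "))
  }
  counts <- lapply(seq_along(matrices), function(i)
    list(dataset = dataset_labels[i],
         retained = length(shared),
         dropped = length(rows[[i]]) - length(shared)))
  nes <- do.call(cbind, lapply(matrices, function(m)
    m$nes[shared, , drop = FALSE]))
  anns <- lapply(seq_along(matrices), function(i) {
    a <- matrices[[i]]$annotations
    a$dataset <- dataset_labels[i]
    a
  })
  cols <- unique(unlist(lapply(anns, names)))
  anns <- lapply(anns, function(a) {
    a[setdiff(cols, names(a))] <- NA
    a[cols]
  })
  ann <- do.call(rbind, anns)
  ann$cell_id_original <- ann$cell_id
  if (anyDuplicated(ann$cell_id)) {
    src <- rep(seq_along(matrices),
               vapply(matrices, function(m) ncol(m$nes), integer(1)))
    dup <- duplicated(ann$cell_id) | duplicated(ann$cell_id, fromLast = TRUE)
    ann$cell_id[dup] <- sprintf("%s#%d", ann$cell_id[dup], src[dup])
  }
  colnames(nes) <- ann$cell_id
  bpa_matrix(nes, annotations = ann,
             provenance = prov_add(list(), "merge_bpa",
                                   n_matrices = length(matrices),
                                   shared_sets = length(shared),
                                   per_matrix = counts))
}

#' Read a two-column ortholog mapping table
#'
#' @param path TSV with a header and two columns: gene symbol in species A,
#'   orthologous symbol in species B. Duplicate pairs are removed;
#'   one-to-many mappings are permitted but reported via a message.
#' @return Data frame of class `ortholog_table` with columns `a` and `b`.
#' @export
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stopf("ortholog table not found: %s", path)
  df <- read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stopf("ortholog table needs two columns")
  ortholog_table(df[[1]], df[[2]])
}

#' @rdname read_ortholog_table
#' @param a,b Equal-length character vectors of paired symbols.
#' @export
ortholog_table <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0L)
    stopf("need equal-length, non-empty symbol vectors")
  df <- unique(data.frame(a = as.character(a), b = as.character(b),
                          stringsAsFactors = FALSE))
  n1m <- sum(duplicated(df$a)) + sum(duplicated(df$b))
  if (n1m > 0)
    message(sprintf("ortholog table: %d one-to-many mapping(s)", n1m))
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Collapse an expression matrix into an orthologous gene namespace
#'
#' The ortholog-based baseline that BPA is compared against: genes are
#' renamed into the other species' symbols via the mapping table, genes
#' without a mapping are dropped, and several source genes mapping to one
#' target symbol are averaged.
#'
#' @param expr An `expr_matrix` (or matrix).
#' @param table An `ortholog_table` (columns `a`, `b`).
#' @param direction `"a_to_b"` renames column-`a` symbols into the `b`
#'   namespace; `"b_to_a"` the reverse.
#' @return An `expr_matrix` in the target namespace; dropped and collided
#'   gene counts are recorded in provenance.
#' @export
collapse_orthologs <- function(expr, table, direction = c("a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  v <- as_expr_values(expr)
  from <- if (direction == "a_to_b") table$a else table$b
  to <- if (direction == "a_to_b") table$b else table$a
  idx <- match(rownames(v), from)
  mapped <- !is.na(idx)
  if (!any(mapped))
    stopf("no gene of the expression matrix appears in the ortholog table")
  tgt <- to[idx[mapped]]
  vm <- v[mapped, , drop = FALSE]
  collided <- sum(duplicated(tgt))
  out <- rowsum(vm, tgt)
  out <- out / as.vector(table(tgt)[rownames(out)])
  out <- out[unique(tgt), , drop = FALSE]  # first-occurrence row order
  expression_matrix(
    out,
    log_base_note = if (inherits(expr, "expr_matrix")) expr$log_base_note
                    else "",
    provenance = prov_add(
      if (inherits(expr, "expr_matrix")) expr$provenance else list(),
      "collapse_orthologs", direction = direction,
      dropped = sum(!mapped), collided = collided,
      collision_rule = "mean"))
}
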