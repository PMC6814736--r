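#' Construct an expression matrix
#'
#' Thin container for a genes x cells matrix of log-scale, non-negative
#' expression values (e.g. log2(TPM+1)). Row and column names are the gene
#' and cell identifiers and must be unique; values must be finite and >= 0.
#'
#' @param values Numeric matrix, genes in rows, cells in columns, with
#'   dimnames set.
#' @param log_base_note Free-text provenance note on the log scale.
#' @param provenance Optional list of provenance records.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, log_base_note = "", provenance = list()) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate cell ids")
  if (!all(is.finite(values))) stopf("expression values must be finite")
  if (min(values) < 0) stopf("expression values must be >= 0 (log scale)")
  structure(list(values = values, log_base_note = log_base_note,
                 provenance = provenance),
            class = "expr_matrix")
}

# Accept either an expr_matrix or a plain named matrix.
as_expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values
  else if (is.matrix(x)) expression_matrix(x)$values
  else stopf("expected an expr_matrix or a genes x cells matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells%s\n",
              nrow(x$values), ncol(x$values),
              if (nzchar(x$log_base_note))
                paste0(" [", x$log_base_note, "]") else ""))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and cell identifiers
#' @param x An `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(as_expr_values(x))

#' @rdname gene_ids
#' @export
cell_ids <- function(x) colnames(as_expr_values(x))

#' Read a dense expression table
#'
#' Expects a TSV/CSV with gene ids in the first column and one column per
#' cell (header row of cell ids).
#'
#' @param path File path.
#' @param sep Field separator (tab by default).
#' @param log_base_note Provenance note on the log scale of the values.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, sep = "\t", log_base_note = "") {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE)
  expression_matrix(as.matrix(df), log_base_note = log_base_note,
                    provenance = prov_add(list(), "read_expression_tsv",
                                          path = path))
}

#' Write a dense expression table (genes x cells TSV)
#' @param x An `expr_matrix` or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  v <- as_expr_values(x)
  write.table(data.frame(gene = rownames(v), v, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket sparse expression matrix
#'
#' Reads the 10x-style triplet of files: an MTX matrix plus plain-text
#' sidecars listing the gene (feature) ids and cell barcodes, one per line.
#' The matrix is densified; ranking materializes full columns anyway, so
#' BPA gains nothing from keeping the input sparse.
#'
#' @param mtx_path MatrixMarket file.
#' @param features_path,barcodes_path One id per line; features may be a
#'   multi-column TSV, in which case the first column is used.
#' @param log_base_note Provenance note.
#' @return An `expr_matrix`.
#' @export
read_expression_mtx <- function(mtx_path, features_path, barcodes_path,
                                log_base_note = "") {
  for (p in c(mtx_path, features_path, barcodes_path))
    if (!file.exists(p)) stopf("file not found: %s", p)
  m <- as.matrix(Matrix::readMM(mtx_path))
  feats <- read.delim(features_path, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  bcs <- readLines(barcodes_path, warn = FALSE)
  bcs <- bcs[nzchar(bcs)]
  if (nrow(m) != length(feats) || ncol(m) != length(bcs))
    stopf("MTX dims %dx%d do not match %d features / %d barcodes",
          nrow(m), ncol(m), length(feats), length(bcs))
  dimnames(m) <- list(feats, bcs)
  expression_matrix(m, log_base_note = log_base_note,
                    provenance = prov_add(list(), "read_expression_mtx",
                                          path = mtx_path))
}
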