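#' Construct a gene set
#'
#' A gene set is a named, ordered collection of unique gene symbols together
#' with free-text description and species/collection tags. Gene symbols are
#' treated case-sensitively throughout the package: cross-species comparison
#' happens at the level of shared gene-set *names*, never at the gene level,
#' so no symbol normalization is attempted.
#'
#' @param name Non-empty set identifier.
#' @param genes Character vector of gene symbols; duplicates are removed
#'   preserving first occurrence.
#' @param description Free text.
#' @param species_tag,collection_tag Provenance tags (e.g. `"C5-BP"`).
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, description = "", species_tag = "",
                     collection_tag = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("gene set name must be a non-empty string")
  genes <- as.character(genes)
  genes <- genes[nzchar(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0L)
    stopf("gene set '%s' has no genes after deduplication", name)
  structure(
    list(name = name, description = description, genes = genes,
         species_tag = species_tag, collection_tag = collection_tag),
    class = "gene_set")
}

#' Construct a gene-set collection
#'
#' @param sets List of [gene_set()] objects with unique names.
#' @param species_tag Species tag shared by all sets (sets are re-tagged).
#' @param provenance List of provenance records (source path, filter
#'   history); maintained automatically by the filtering functions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, species_tag = "", provenance = list()) {
  if (!is.list(sets)) stopf("'sets' must be a list of gene_set objects")
  ok <- vapply(sets, inherits, logical(1), what = "gene_set")
  if (length(sets) && !all(ok)) stopf("all elements must be gene_set objects")
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stopf("duplicate gene set name(s): %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(sets, function(s) { s$species_tag <- species_tag; s })
  names(sets) <- nm
  structure(list(sets = sets, species_tag = species_tag,
                 provenance = provenance),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Sizes of the sets in a collection
#' @param coll A `gene_set_collection`.
#' @return Named integer vector of per-set gene counts.
#' @export
set_sizes <- function(coll) {
  vapply(coll$sets, function(s) length(s$genes), integer(1))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- set_sizes(x)
  cat(sprintf("gene_set_collection: %d sets [species: %s]\n",
              length(x), ifelse(nzchar(x$species_tag), x$species_tag, "?")))
  if (length(x))
    cat(sprintf("  set sizes: min %d / median %s / max %d\n",
                min(sz), format(stats::median(sz)), max(sz)))
  cat(sprintf("  provenance: %d record(s)\n", length(x$provenance)))
  invisible(x)
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT interchange format (one set per line:
#' name, description, then gene symbols). Duplicate symbols within a line
#' are removed preserving first occurrence; duplicate set names are an
#' error. Blank lines are skipped.
#'
#' @param path Path to a GMT file.
#' @param species_tag,collection_tag Tags recorded on every set.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, species_tag = "", collection_tag = "") {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- vector("list", sum(keep))
  k <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- sub("[[:space:]]+$", "", fields)
    if (length(fields) < 3L)
      stopf("%s: line %d: expected >= 3 tab-separated fields, got %d",
            path, i, length(fields))
    k <- k + 1L
    sets[[k]] <- gene_set(fields[1], fields[-(1:2)],
                          description = fields[2],
                          species_tag = species_tag,
                          collection_tag = collection_tag)
  }
  nm <- vapply(sets[seq_len(k)], `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stopf("%s: duplicate set name(s): %s", path,
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  gene_set_collection(
    sets[seq_len(k)], species_tag = species_tag,
    provenance = prov_add(list(), "read_gmt", path = path, n_sets = k))
}

#' Write a collection to GMT, with a JSON provenance sidecar
#'
#' @param coll A `gene_set_collection`.
#' @param path Output GMT path; provenance is written to `<path>.prov.json`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(coll$sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  jsonlite::write_json(coll$provenance, paste0(path, ".prov.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Filter gene sets by size
#'
#' Retains sets whose gene count lies inside the inclusive window
#' `[min_size, max_size]`. Size windows counter two opposing biases of
#' rank-sum enrichment: very large sets receive inflated activities, while
#' very small sets yield noisy activities (their coefficient of variation
#' grows as size shrinks). Typical windows are 50-100 genes for GO
#' Biological Process sets and 190-210 for immunologic signature sets.
#'
#' @param coll A `gene_set_collection`.
#' @param min_size,max_size Inclusive bounds, `1 <= min_size <= max_size`.
#' @return Filtered collection; the window is recorded in provenance. An
#'   empty result is returned with a warning, not an error.
#' @export
filter_by_size <- function(coll, min_size, max_size) {
  if (min_size < 1 || min_size > max_size)
    stopf("need 1 <= min_size <= max_size (got %s, %s)", min_size, max_size)
  sz <- set_sizes(coll)
  keep <- sz >= min_size & sz <= max_size
  if (!any(keep))
    warnf("filter_by_size [%d,%d]: no sets retained", min_size, max_size)
  gene_set_collection(
    unname(coll$sets[keep]), species_tag = coll$species_tag,
    provenance = prov_add(coll$provenance, "filter_by_size",
                          min_size = min_size, max_size = max_size,
                          inclusive = TRUE,
                          n_before = length(coll), n_after = sum(keep)))
}

#' Keep only up-regulated gene sets
#'
#' Immunologic signature collections ship paired `_UP`/`_DN` sets. Because
#' drop-out makes lowly expressed genes unreliable in single-cell data,
#' only the up-regulated member of each pair is kept (and the pairing
#' redundancy removed). Matching is a case-sensitive name-suffix test; an
#' empty suffix retains everything.
#'
#' @param coll A `gene_set_collection`.
#' @param suffix Name suffix identifying up-sets (default `"_UP"`).
#' @return Filtered collection (warning if empty).
#' @export
keep_upregulated <- function(coll, suffix = "_UP") {
  keep <- if (nzchar(suffix)) {
    endsWith(vapply(coll$sets, `[[`, character(1), "name"), suffix)
  } else rep(TRUE, length(coll))
  if (!any(keep) && length(coll))
    warnf("keep_upregulated('%s'): no sets retained", suffix)
  gene_set_collection(
    unname(coll$sets[keep]), species_tag = coll$species_tag,
    provenance = prov_add(coll$provenance, "keep_upregulated",
                          suffix = suffix,
                          n_before = length(coll), n_after = sum(keep)))
}

#' Restrict gene sets to a measured-gene universe
#'
#' Intersects every set with the genes actually present in an expression
#' matrix and drops sets left with fewer than `min_overlap` members. Below
#' roughly 5 members the enrichment score is the average of only a handful
#' of rank quantiles and stops being a meaningful ensemble statistic.
#'
#' @param coll A `gene_set_collection`.
#' @param universe Non-empty character vector of measured gene symbols.
#' @param min_overlap Minimum post-intersection size to retain a set.
#' @return Filtered collection; original and retained sizes per set are
#'   recorded in provenance.
#' @export
restrict_to_universe <- function(coll, universe, min_overlap = 5L) {
  if (length(universe) == 0L) stopf("universe must be non-empty")
  universe <- as.character(universe)
  sizes0 <- set_sizes(coll)
  sets <- lapply(coll$sets, function(s) {
    s$genes <- s$genes[s$genes %in% universe]
    s
  })
  sizes1 <- vapply(sets, function(s) length(s$genes), integer(1))
  keep <- sizes1 >= min_overlap
  gene_set_collection(
    unname(sets[keep]), species_tag = coll$species_tag,
    provenance = prov_add(
      coll$provenance, "restrict_to_universe",
      universe_size = length(unique(universe)), min_overlap = min_overlap,
      n_before = length(coll), n_after = sum(keep),
      original_sizes = as.list(sizes0), retained_sizes = as.list(sizes1)))
}
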