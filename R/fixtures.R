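#' Specification for the synthetic fixture generators
#'
#' The generators emulate the structure the BPA analyses assume: cell
#' states driven by the activity of gene *sets* (not individual markers),
#' with technical batch offsets and Gaussian measurement noise layered on
#' top, all in log-expression space. Values are log-normal-like (Gaussian
#' in log space, floored at 0); count-level realism is irrelevant to a
#' rank-based transform and deliberately not modeled.
#'
#' Defaults describe a modest three-cell-type experiment: 3 x 100 cells,
#' 2000 genes, 30 disjoint sets of 60 genes, an activity effect of 1 log2
#' unit on active-set members, per-gene batch offsets with SD 0.5 log2
#' units (a typical chemistry/platform shift), measurement noise SD 0.5,
#' and gene baselines N(2, 1) in log2 units.
#'
#' @param n_cell_types,cells_per_type,n_genes,n_sets,genes_per_set Counts.
#' @param activity_effect Mean log-expression shift of active-set member
#'   genes in their cell type.
#' @param batch_shift SD of the per-gene additive batch offset.
#' @param noise_sd SD of per-entry Gaussian noise.
#' @param dropout_rate_target Nominal overall drop-out fraction the default
#'   curve aims for when drop-outs are injected downstream.
#' @param n_batches Number of batches cells are interleaved into.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @param seed Integer seed; generators are deterministic given it.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_cell_types = 3L, cells_per_type = 100L,
                         n_genes = 2000L, n_sets = 30L, genes_per_set = 60L,
                         activity_effect = 1.0, batch_shift = 0.5,
                         noise_sd = 0.5, dropout_rate_target = 0.8,
                         n_batches = 1L, baseline_mean = 2, baseline_sd = 1,
                         seed = 7L) {
  spec <- list(n_cell_types = as.integer(n_cell_types),
               cells_per_type = as.integer(cells_per_type),
               n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
               genes_per_set = as.integer(genes_per_set),
               activity_effect = activity_effect, batch_shift = batch_shift,
               noise_sd = noise_sd,
               dropout_rate_target = dropout_rate_target,
               n_batches = as.integer(n_batches),
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               seed = as.integer(seed))
  counts <- unlist(spec[c("n_cell_types", "cells_per_type", "n_genes",
                          "n_sets", "genes_per_set", "n_batches")])
  if (any(counts < 1L)) stopf("all counts must be positive")
  if (!all(is.finite(unlist(spec[c("activity_effect", "batch_shift",
                                   "noise_sd")]))))
    stopf("effect sizes must be finite")
  if (spec$genes_per_set > spec$n_genes)
    stopf("genes_per_set exceeds n_genes")
  structure(spec, class = "fixture_spec")
}

# Shared layout: disjoint gene blocks per set, contiguous blocks of sets
# per cell type; errors if the disjoint layout is infeasible.
fixture_layout <- function(spec) {
  if (spec$n_sets * spec$genes_per_set > spec$n_genes)
    stopf("infeasible: %d sets x %d genes/set > %d genes (disjoint blocks)",
          spec$n_sets, spec$genes_per_set, spec$n_genes)
  set_genes <- lapply(seq_len(spec$n_sets), function(i)
    ((i - 1L) * spec$genes_per_set + 1L):(i * spec$genes_per_set))
  set_type <- sort(rep_len(seq_len(spec$n_cell_types), spec$n_sets))
  list(set_genes = set_genes, set_type = set_type)
}

fixture_collection <- function(gene_names, layout, spec, species_tag) {
  sets <- lapply(seq_len(spec$n_sets), function(i) {
    gene_set(sprintf("BP_SET_%03d", i),
             gene_names[layout$set_genes[[i]]],
             description = sprintf("synthetic marker set for type%d",
                                   layout$set_type[i]),
             species_tag = species_tag, collection_tag = "synthetic")
  })
  gene_set_collection(sets, species_tag = species_tag,
                      provenance = prov_add(list(), "make_fixture",
                                            spec = unclass(spec)))
}

#' Multi-cell-type expression fixture with batch structure
#'
#' Generates a genes x cells matrix in which each cell type is defined by
#' a disjoint block of "marker" gene sets: member genes of a type's active
#' sets have mean `baseline + activity_effect` in that type, everything
#' else sits at baseline. Cells are interleaved across `n_batches`
#' batches, each contributing an independent per-gene additive offset of
#' SD `batch_shift`; Gaussian noise of SD `noise_sd` is added per entry
#' and values are floored at 0.
#'
#' @param spec A [fixture_spec()].
#' @return List with `expr` (an `expr_matrix`), `genesets` (a
#'   `gene_set_collection`), `annotations` (cell_id, cell_type, dataset =
#'   batch, species) and `truth` (set-to-type assignment).
#' @export
make_celltype_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  layout <- fixture_layout(spec)
  with_seed(spec$seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    n_cells <- spec$n_cell_types * spec$cells_per_type
    cells <- sprintf("cell_%04d", seq_len(n_cells))
    type <- rep(seq_len(spec$n_cell_types), each = spec$cells_per_type)
    batch <- rep_len(seq_len(spec$n_batches), n_cells)
    baseline <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    mu <- matrix(baseline, spec$n_genes, n_cells)
    for (i in seq_len(spec$n_sets)) {
      idx <- layout$set_genes[[i]]
      on <- type == layout$set_type[i]
      mu[idx, on] <- mu[idx, on] + spec$activity_effect
    }
    if (spec$n_batches > 1L) {
      offs <- matrix(rnorm(spec$n_genes * spec$n_batches,
                           0, spec$batch_shift),
                     spec$n_genes, spec$n_batches)
      mu <- mu + offs[, batch]
    }
    v <- mu + matrix(rnorm(length(mu), 0, spec$noise_sd),
                     spec$n_genes, n_cells)
    v[v < 0] <- 0
    dimnames(v) <- list(genes, cells)
    list(
      expr = expression_matrix(v, log_base_note = "synthetic log2-like",
                               provenance = prov_add(list(),
                                                     "make_celltype_fixture",
                                                     spec = unclass(spec))),
      genesets = fixture_collection(genes, layout, spec, "synthetic"),
      annotations = data.frame(
        cell_id = cells,
        cell_type = sprintf("type%d", type),
        dataset = sprintf("batch%d", batch),
        species = "speciesA", stringsAsFactors = FALSE),
      truth = list(set_type = layout$set_type))
  })
}

#' Two-"species" fixture with disjoint gene namespaces
#'
#' Emulates the cross-species setting: the same latent cell types drive
#' both datasets, but the two gene namespaces are disjoint by construction
#' (prefixes `gA_`/`gB_`), so any alignment must happen through shared
#' gene-set *names*. Each species gets its own gene-set collection; the
#' collections share set names, and within each species only a fraction
#' `conserved_fraction` of a set's members actually respond to the latent
#' activity (partial conservation of set membership semantics). Each
#' species also receives an independent per-gene offset of SD
#' `species_shift`, standing in for the platform-plus-species shift that
#' makes raw expression incomparable across datasets — chosen larger than
#' the within-study `batch_shift` default.
#'
#' @param spec A [fixture_spec()].
#' @param conserved_fraction Fraction of each set's members carrying the
#'   latent activity in each species.
#' @param species_shift SD of the per-gene, per-species additive offset.
#' @return List with `expr_a`, `expr_b`, `sets_a`, `sets_b`, combined
#'   `annotations`, `ortholog_table` (index-matched gA/gB pairs, for the
#'   ortholog-collapse baseline) and `truth`.
#' @export
make_two_species_fixture <- function(spec = fixture_spec(),
                                     conserved_fraction = 0.8,
                                     species_shift = 1.0) {
  stopifnot(inherits(spec, "fixture_spec"))
  layout <- fixture_layout(spec)
  with_seed(spec$seed, {
    n_cells <- spec$n_cell_types * spec$cells_per_type
    type <- rep(seq_len(spec$n_cell_types), each = spec$cells_per_type)
    baseline <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    one_species <- function(tag) {
      genes <- sprintf("g%s_%04d", tag, seq_len(spec$n_genes))
      cells <- sprintf("cell%s_%04d", tag, seq_len(n_cells))
      shift <- rnorm(spec$n_genes, 0, species_shift)
      mu <- matrix(baseline + shift, spec$n_genes, n_cells)
      respond <- lapply(layout$set_genes, function(idx)
        sort(sample(idx, max(1L, round(conserved_fraction * length(idx))))))
      for (i in seq_len(spec$n_sets)) {
        on <- type == layout$set_type[i]
        mu[respond[[i]], on] <- mu[respond[[i]], on] + spec$activity_effect
      }
      v <- mu + matrix(rnorm(length(mu), 0, spec$noise_sd),
                       spec$n_genes, n_cells)
      v[v < 0] <- 0
      dimnames(v) <- list(genes, cells)
      list(genes = genes, cells = cells, v = v, respond = respond)
    }
    a <- one_species("A")
    b <- one_species("B")
    ann <- data.frame(
      cell_id = c(a$cells, b$cells),
      cell_type = sprintf("type%d", c(type, type)),
      dataset = rep(c("datasetA", "datasetB"), each = n_cells),
      species = rep(c("speciesA", "speciesB"), each = n_cells),
      stringsAsFactors = FALSE)
    prov <- prov_add(list(), "make_two_species_fixture",
                     spec = unclass(spec),
                     conserved_fraction = conserved_fraction,
                     species_shift = species_shift)
    list(
      expr_a = expression_matrix(a$v, "synthetic log2-like", prov),
      expr_b = expression_matrix(b$v, "synthetic log2-like", prov),
      sets_a = fixture_collection(a$genes, layout, spec, "speciesA"),
      sets_b = fixture_collection(b$genes, layout, spec, "speciesB"),
      annotations = ann,
      ortholog_table = ortholog_table(a$genes, b$genes),
      truth = list(set_type = layout$set_type,
                   respond_a = a$respond, respond_b = b$respond))
  })
}

#' Staged trajectory fixture for dynamic time warping
#'
#' Samples a smooth latent activity trajectory on a reference grid of
#' `n_stages_a` stages and re-samples it on a second grid through a
#' monotone warp, producing two feature-matched stage-profile sequences
#' whose ground-truth alignment path is known. `warp[j] = i` means stage j
#' of sequence B corresponds to stage i of sequence A; the warp must be
#' monotone non-decreasing, start at 1, end at `n_stages_a`, and advance
#' in steps of 0 or 1 (i.e. be surjective), so the ground-truth path is
#' exactly `cbind(warp, seq_along(warp))`.
#'
#' @param n_stages_a,n_stages_b Stage counts (B implied by `warp` length).
#' @param warp Integer vector of length `n_stages_b`.
#' @param spec A [fixture_spec()] (uses `n_sets` as feature count,
#'   `noise_sd`, `seed`).
#' @return List with `seq_a`, `seq_b` (stages x features matrices),
#'   `warp` and `path_truth`.
#' @export
make_stage_fixture <- function(n_stages_a, warp, spec = fixture_spec(),
                               n_stages_b = length(warp)) {
  stopifnot(inherits(spec, "fixture_spec"))
  warp <- as.integer(warp)
  if (length(warp) != n_stages_b) stopf("warp length must be n_stages_b")
  d <- diff(warp)
  if (any(d < 0L)) stopf("warp must be monotone non-decreasing")
  if (any(d > 1L) || warp[1] != 1L || warp[length(warp)] != n_stages_a)
    stopf("warp must start at 1, end at n_stages_a, and advance by 0 or 1")
  with_seed(spec$seed, {
    k <- spec$n_sets
    t_a <- seq(0, 1, length.out = n_stages_a)
    amp <- rnorm(k, 0, 1); lin <- rnorm(k, 0, 1); phase <- runif(k, 0, pi)
    f <- function(t) vapply(seq_len(k), function(j)
      lin[j] * t + amp[j] * sin(pi * t + phase[j]), numeric(length(t)))
    base_a <- f(t_a)                     # stages x features
    if (is.null(dim(base_a))) base_a <- matrix(base_a, nrow = 1L)
    seq_a <- base_a + matrix(rnorm(length(base_a), 0, spec$noise_sd),
                             nrow(base_a))
    base_b <- base_a[warp, , drop = FALSE]
    seq_b <- base_b + matrix(rnorm(length(base_b), 0, spec$noise_sd),
                             nrow(base_b))
    rownames(seq_a) <- sprintf("A_stage%02d", seq_len(n_stages_a))
    rownames(seq_b) <- sprintf("B_stage%02d", seq_len(n_stages_b))
    list(seq_a = seq_a, seq_b = seq_b, warp = warp,
         path_truth = cbind(a = warp, b = seq_along(warp)))
  })
}
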