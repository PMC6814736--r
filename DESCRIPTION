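Package: bpa
Title: Biological Process Activity Transformation of Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("BPA", "Maintainers", email = "bpa@example.org", role = c("aut", "cre"))
Description: Transforms per-cell gene expression profiles into z-scored
    biological process activities (BPA) using an analytic rank-based
    enrichment score. Because the resulting normalized enrichment scores are
    approximately standard normal, activity profiles can be merged across
    batches, platforms and species without renormalization, enabling
    ortholog-free cross-species alignment of single-cell states. Includes
    gene-set (GMT) reading and filtering, an expression-dependent drop-out
    simulator, a variance-ratio test of species mixing within cell types,
    classical multidimensional scaling and dendrogram helpers, dynamic time
    warping of staged trajectories, synthetic fixture generators, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
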