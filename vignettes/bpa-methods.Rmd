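---
title: "Biological process activity: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological process activity: model, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpa)
```

## The model

Single-cell RNA-seq expression has poor per-gene signal-to-noise:
batch/platform offsets and drop-out events distort individual transcript
measurements, and gene namespaces differ between species. The biological
process activity (BPA) transform replaces per-gene expression with
per-pathway activity scores built from an ensemble of dozens of related
genes, so that discrepancies in individual genes average out.

For one cell, genes are ranked by that cell's own log expression
(ascending, ties averaged — the zero block typical of sparse single-cell
data forms one tie), ranks are scaled as $r_i/(N+1)$ and mapped through
the standard-normal quantile function to give per-gene values $z_i$. For
a gene set $S$ with $n$ members the normalized enrichment score is

$$\mathrm{NES}(S) = \frac{1}{\sqrt{n}} \sum_{i \in S} z_i ,$$

the analytic z-score of the mean rank quantile over the members. This is
the unsigned-gene-set specialization of analytic rank-based enrichment:
gene sets carry no direction or confidence annotations, so weights are
uniform and every member is treated as positively associated. Under a
random signature the NES of a random set is approximately standard
normal (the acceptance suite verifies mean, SD and a KS test against
N(0,1)), which is precisely what licenses concatenating BPA matrices
across datasets — and across species, via shared gene-set *names* —
without any renormalization.

Two modeling commitments deserve emphasis:

* **Single-sample signatures.** Each cell is ranked against itself; the
  dataset-average signature is *not* subtracted. A differential
  signature would make every cell's activities depend on the composition
  of the dataset it happens to sit in, which is exactly what
  cross-dataset integration cannot afford. The differential mode exists
  behind `bpa_transform(..., relative = TRUE)` for comparison
  experiments only.
* **Rank invariance.** The transform depends on expression only through
  within-cell ranks, so any strictly monotone per-cell transform
  (log base, scaling, library-size normalization that preserves order)
  leaves the output unchanged. This is tested as a property.

### Numerical conventions the source method leaves open

The rank step inside the enrichment machinery is not fully pinned down
upstream, so the package fixes and records these conventions:

* **Rank scaling** is $r/(N+1)$, not $(r-0.5)/N$: quantiles stay finite
  and symmetric, and a tie-free signature's $z$ sum to exactly 0.
* **Ties** get the mean of their rank positions, preserving quantile
  symmetry; an all-tied (flat) cell yields all-zero $z$ with a warning.
* Both choices are written into the provenance chain of every
  `bpa_matrix`.

## Gene-set handling

Collections are read from GMT files and filtered with inclusive size
windows (typically 50–100 genes for GO-BP style sets, 190–210 for
immunologic signatures): large sets receive inflated activities from a
rank-sum score, while small sets are noisy — the coefficient of
variation of the NES grows as set size shrinks, a relationship the
acceptance suite demonstrates directly at sizes 10/50/100. For paired
up/down immunologic signatures, only `_UP` sets are kept (drop-out makes
underexpressed genes unreliable; the suffix is configurable). Before
scoring, sets are intersected with the measured universe and dropped
below `min_overlap = 5` members — under that, the NES is an average of a
handful of quantile draws, not an ensemble statistic. Whether the
upstream size windows were inclusive is not documented; inclusivity is
chosen here and recorded in provenance so realized set counts are
auditable against any particular MSigDB release.

Shadow analysis (down-weighting overlapping sets) is deliberately
omitted: weighted and unweighted activities were reported upstream to
differ very little, and unweighted sets keep every set's gene
complement intact.

## The species-mixing F test

With cells described by $q$ features, the pooled within-group variance
under a labeling with $M$ groups is the summed squared Euclidean
distance of cells to their group centroids divided by $N - M$; for one
feature this is the classic ANOVA within-group mean square. The test
computes this under the cell-type labeling ($V_t$, $M_t$ groups) and the
dataset/species labeling ($V_s$, $M_s$ groups) and reports

$$F = V_s / V_t,$$

referred, one-sided, to an F distribution with $(N-M_t,\ N-M_s)$
degrees of freedom. $F \gg 1$ means cells of the same type are far
tighter than cells of the same dataset — species mix within cell types.

**Orientation.** The upstream description labels the ratio $V_t/V_s$
while stating that values above one indicate tight cell types; those two
statements are arithmetically incompatible (tight cell types mean
*small* $V_t$, which must sit in the denominator to push the ratio above
one). The implementation follows the stated interpretation, not the
label order, and says so in the result object's `orientation` field.

**Calibration caveat — and a deliberately red acceptance test.** Both
variances are computed from the *same* cells. Writing $SS_t = SS_{tot} -
B_t$ and $SS_s = SS_{tot} - B_s$ (between-group sums of squares $B$ have
only $M-1$ degrees of freedom each), the shared total-scatter term
dominates both and largely cancels in the ratio, so under an exchangeable
null $F$ concentrates near 1 *much* more tightly than an
$F(N-M_t, N-M_s)$ variate; null p-values pile up near 0.5 instead of
being uniform. Simulation across sample sizes, feature counts and group
configurations confirms this without exception. The acceptance suite
nevertheless contains the uniformity test exactly as its contract states
it, and that one expectation fails by construction — an honest negative
result about the statistic itself. Practical reading: the p-value is a
descriptive index that is strongly *conservative* for moderate effects;
the enormous F ratios produced by real cell-type structure (the fixture
reproduces the $p \approx 10^{-12}$ regime) are unaffected by the
caveat.

## Drop-out simulation

Drop-out probability is modeled as a four-parameter decreasing logistic
in log expression,

$$p(x) = \mathrm{floor} + \frac{\mathrm{ceiling} - \mathrm{floor}}
  {1 + e^{\mathrm{slope}\,(x - \mathrm{midpoint})}},$$

the simplest monotone-decreasing family with saturating tails that can
be fit from data and documented in two lines. The upstream relationship
was determined empirically and never printed; only its decreasing shape
and the resulting ~81–83% overall rates are known, so
`default_dropout_curve()` (midpoint 4, slope 1, ceiling 0.95,
floor 0.05, in log2 units) is calibrated to land fixtures with
baseline $\mathcal{N}(2,1)$ in that ~80% regime. Injection zeroes each
*non-zero* entry independently with probability $p(\text{its own
value})$ — the drop-out chance of a transcript depends on its own
expression level — and is deterministic given a seed.

Fitting reverses this: per gene, the mean log expression over detected
cells is paired with the fraction of zeros, points are pooled into ≥ 20
equal-count bins, and the logistic is fit by bounded least squares.
Identifiability requires the data to sample both plateaus: a design
whose expression range never reaches the floor cannot recover it (the
acceptance recovery test spans 0–8 log units for this reason), and a
flat drop-out profile leaves midpoint/slope undetermined — detected and
warned about rather than reported as a confident fit.

## Cross-species machinery

`merge_bpa` concatenates matrices on the intersection of set names (in
the first matrix's order) and copies NES values bit-for-bit: a union
would create structurally missing blocks that poison downstream
distances, and any rescaling would contradict the z-score rationale for
merging. The ortholog baseline (`collapse_orthologs`) renames genes via
a two-column table, drops unmapped genes and resolves many-to-one
collisions by averaging — the upstream account is silent on collisions;
averaging is the choice least likely to manufacture signal, and counts
are recorded in provenance.

Staged trajectories are compared by standard dynamic time warping
(steps (1,0), (0,1), (1,1), no window), with ties broken diagonal-first
so the reported path is deterministic. Cells are aggregated per stage by
the mean BPA vector (`stage_profiles`; median available) — the upstream
aggregation is unstated, and the mean is the natural companion of
Euclidean stage distances.

## What the synthetic fixtures do and do not establish

The generators build log-scale matrices in which cell identity is
injected *through gene sets*: each cell type activates a disjoint block
of sets (+1 log2 unit on members by default), over per-gene baselines
$\mathcal{N}(2,1)$, with per-gene batch offsets (SD 0.5, a typical
chemistry shift), per-entry noise (SD 0.5) and flooring at 0. The
two-species fixture uses disjoint gene namespaces (`gA_`/`gB_`), shares
set names across species with 80% of members responding per species
(partial conservation), and applies an independent per-gene species
offset of SD 1.0 — larger than a within-study batch, standing in for the
platform-plus-species shift that makes raw expression incomparable.

Because ground truth lives in pathway space by construction, a green
cross-species test establishes that the *machinery* recovers set-level
structure through disjoint namespaces, drop-out and batch shifts. It
does not establish that real GO-BP terms are functionally equivalent
across real species, that real drop-out follows a logistic, or anything
about library-size/UMI artifacts, ambient RNA or doublets — none of
which are modeled. Count-level realism is irrelevant to a rank-based
transform and intentionally absent.

## Degenerate inputs and determinism

* Flat cells (all genes tied) score 0 on every set, with a warning.
* `select_by_sd` breaks SD ties by set name; MDS axes have their
  largest-magnitude loading forced positive; DTW tie-breaks prefer the
  diagonal — every reported object is reproducible bit-for-bit.
* All stochastic operations take an explicit seed and restore the
  caller's RNG state.
* Empty filter results warn rather than error (an empty collection is a
  legitimate, auditable outcome of a size window); an empty *overlap*
  with the measured universe errors, listing per-set counts, since no
  transform is possible.

## Known limitations

* The F-test p-value calibration issue described above is a property of
  the statistic's construction, not of the implementation.
* `fit_dropout_curve` assumes genes cluster around a characteristic
  expression level; genes whose expression is strongly bimodal across
  cells blur the empirical curve.
* Very small universes (tens of genes) make NES granular; the
  `min_overlap` guard protects against the worst of it but cannot make
  a 20-gene transcriptome informative.
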