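---
title: "Comparing sequencing experiments against reference compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing sequencing experiments against reference compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcor)
```

## The model

`seqcor` treats "which experiments does my sample resemble?" as a
correlation problem in a fixed feature space. A *compendium* is a
feature × experiment matrix **M** plus per-experiment metadata; the three
assay types map onto it differently:

* **Expression (RNA-seq).** Features are normalized gene identifiers
  (case-folded, trailing `.N` version suffix stripped); the entry for
  gene *g* in experiment *e* is `log2(FPKM_ge + 1)`. Genes absent from an
  experiment contribute raw 0 *before* the transform, so every column
  lives in the identical feature space.
* **ChIP-seq peaks.** Features are the *region universe*: the union of
  all reference peak sets with overlapping or bookended intervals merged,
  sorted by (chrom, start). The entry is 1 iff the experiment has a peak
  overlapping the region by at least one base. All coordinates are
  0-based half-open and never converted; two intervals overlap iff
  `max(starts) < min(ends)`, so bookended intervals share no base but are
  still merged during universe construction (they describe contiguous
  signal).
* **CAGE.** Same region universe; the entry is
  `log2(sum of peak scores in the region + 1)` — scores of multiple
  intervals falling in one region are summed before the log.

Similarity between two columns (or a projected user sample and a column)
is the Pearson product-moment coefficient; on binary vectors this equals
the phi coefficient, so one statistic serves all three assay types. A
vector with zero variance (for instance a user peak file that misses the
universe entirely) has no defined correlation; `seqcor` reports these as
explicitly *undefined* (`NA`), ranks them last and excludes them from
clustering — reporting 0 would fabricate a rank.

## Projection: the frozen-universe contract

A user sample becomes comparable by *projection* onto the compendium's
feature index: expression values are matched by normalized gene ID
(unmatched user genes are dropped and counted; missing compendium genes
filled with raw 0), peaks are binarized over the universe, CAGE scores
are summed per region; then the compendium's own transform (recorded in
its on-disk manifest) is applied. The universe and gene index are frozen
at build time. This has two consequences worth stating plainly: reference
correlations can never change because a user file arrived, and projecting
a reference experiment's own raw input reproduces its column exactly —
a property the test suite checks bit-exactly for all three types.

Projection returns a coverage report (features matched/filled, user items
matched/unmatched). A user peak file that overlaps nothing is a warning,
not an error: the projection is all-zero and its correlation undefined,
which is the honest answer.

## Clustering and display order

Experiments are ordered by agglomerative hierarchical clustering on the
correlation distance d = 1 − r, the standard choice that keeps
anti-correlated samples maximally distant. Four linkages are exposed:
complete (default, the common heatmap choice), average, single and Ward
(applied to squared distances with a square-root back-transform, i.e. the
`ward.D2` convention). The implementation is deliberately deterministic:

* among equally close cluster pairs, the pair containing the lowest
  original column indices merges first;
* in the leaf order, the subtree holding the lowest original index is
  drawn first;
* experiments with undefined correlations are excluded from clustering
  and appended at the end of the ordering.

These conventions make outputs byte-reproducible across runs and
platforms, which is why the clustering is implemented directly
(Lance–Williams updates) rather than delegated: `stats::hclust` computes
the same merge heights — the tests cross-check this on tie-free input —
but does not guarantee this tie-break or leaf-order convention. An
independently coded naive agglomerative oracle, which recomputes every
inter-cluster distance from the original matrix at each step, must agree
with the implementation exactly on random matrices.

## Parameters that matter

* **Pseudocount** (default 1, unit: same as the abundance) and **log
  base** (default 2). "Log-scaled" expression with zero FPKM values
  requires a pseudocount; `log2(x + 1)` is the field's convention, keeps
  entries non-negative, and is recorded in the compendium manifest so a
  projection always applies the transform its compendium was built with.
  Pseudocounts below 1 are rejected because they would make the log of
  empty features negative.
* **Overlap threshold**: ≥ 1 bp, the permissive default; region
  membership is binary presence, not coverage fraction.
* **Linkage** (default complete) — see above.
* **Label policy**: heatmap labels auto-hide above 80 experiments
  (configurable); the color scale is a diverging blue–white–red ramp
  anchored at exactly [−1, 1] regardless of the data range, so figures
  from different runs and subsets share one color key; undefined entries
  are drawn in a distinct grey, never as numeric 0.

## The synthetic generator

Real compendia are built from thousands of public experiments; for
development and validation `seqcor` generates compendia with *planted*
structure. Experiment *e* of group *g* draws, per feature,

    x_e = sqrt(rho_out) * z_global + sqrt(rho_in - rho_out) * z_g
          + sqrt(1 - rho_in) * eps_e

with independent standard normal latents, so within-group correlation is
ρ_in and between-group correlation ρ_out in expectation — closed-form
control, not tuning. Expression and CAGE values are
`2^(log_mean + log_sd * x)` (defaults: log-mean 5, log-sd 2 on the log₂
scale, i.e. FPKM-like values with median ≈ 32), strictly positive so the
`log2(x + 1)` compression distorts little. Peak samples threshold the
latent at `qnorm(1 − density)` (default density 0.5: each sample carries
half of the ~2000 master regions); because dichotomisation attenuates
correlation, the latent correlation is inflated by the tetrachoric
inversion — exact at density 0.5, where ρ_latent = sin(πφ/2) — so the
*realized phi* on the binary matrix lands on the design targets. Master
regions are fixed-width (200 bp) intervals jittered within disjoint slots
on a 3 × 10 Mb genome model, small enough for per-base brute-force
oracles in the tests.

Defaults (5 groups × 4 experiments, 2000 features, ρ_in = 0.8,
ρ_out = 0.1) describe a small but realistic reference set: replicate-level
within-group similarity, weak global background. `perturb_sample()`
produces degraded copies (a fraction of expression values permuted, or of
peaks relocated uniformly on the genome) whose expected correlation with
the source decreases monotonically in the intensity — the
quality-control scenario in miniature.

What the generator does *not* emulate: library-size and GC biases,
zero-inflation of lowly expressed genes, peak-width and signal-strength
heterogeneity, chromosomal clustering of binding sites, and annotation
mismatches between user and reference. Passing the planted-recovery tests
therefore shows the machinery is correct and well-calibrated, not that
any particular biological contrast is detectable in real data.

## Numerical and design choices

* The on-disk compendium is a plain-text directory (`manifest.json`,
  `matrix.tsv`, `features.tsv`, `metadata.tsv`); doubles are written as
  `%.17g`, so write→read round trips are bit-exact.
* Duplicate gene IDs in a user table keep the maximum value (with a
  warning): deterministic and independent of row order.
* Correlations are clamped to [−1, 1] against floating drift; matrices
  keep a unit diagonal by construction.
* One region universe is built per compendium (not per factor or cell
  type); subsetting by metadata selects columns only and never rebuilds
  the universe, so subsetting commutes with correlation.
* Degenerate inputs are first-class: empty peak samples binarize to the
  zero vector, constant columns are undefined rather than dropped
  silently, and zero gene overlap in projection is an error that prints
  example identifiers from both sides (the common symptom of mismatched
  ID schemes).

## Problem sizes used in validation

The test suite validates the primitives against brute-force oracles
(10⁴ random vector pairs for the correlation; 200 random interval
instances on the 10 Mb genome for merge and binarization, plus per-base
coverage checks on a 10 kb genome), projection round-trips on 20
experiments per compendium type, planted-group recovery and clustering
contiguity over 100 generator seeds at the default design, perturbation
monotonicity over 50 seeds, and figure generation from 2×2 up to 500×500
matrices. `scripts/acceptance.R` recomputes the same quantities from a
single `--seed`.

## Known limitations

* Pearson correlation only — no rank-based or count-model similarity; on
  sparse binary vectors phi is sensitive to the universe size.
* No normalization beyond the log transform (no quantile or library-size
  adjustment), no gene-ID translation across annotation systems, no
  coordinate liftover: user input must already be on the compendium's
  annotation/assembly.
* Leaf order is the deterministic dendrogram order; no optimal leaf
  ordering is attempted.
* The clustering is quadratic in memory and cubic in time in the number
  of experiments; it is intended for compendia up to a few hundred
  experiments per figure, with metadata subsetting as the tool for
  narrowing larger collections.
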