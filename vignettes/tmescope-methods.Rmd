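---
title: "Methods: annotation, similarity maps, malignancy, and spatial structure in tmescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation, similarity maps, malignancy, and spatial structure in tmescope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmescope)
```

tmescope implements four connected analyses of the tumor microenvironment
(TME): supervised cell-subtype annotation with transferable templates, a
quantitative similarity map between subtype labels defined in different
studies, reference-free malignant-cell classification, and spatial
transcriptomics structure detection. This vignette explains each model, the
parameters that matter, the numerical conventions, and what the synthetic
generators do and do not emulate.

## Data model and normalization

Expression is carried as a sparse non-negative integer matrix, cells (or
spots) by genes, with unique string identifiers. One normalization is used
everywhere a score is computed: counts scaled to a fixed library size of
10,000 per cell and transformed by `log(1 + x)` (`normalize_counts()`).
That convention is the de facto single-cell standard; we deliberately keep
*raw counts* for multinomial template estimation and likelihood
classification, because the classifier is a multinomial model of transcript
counts and is count-native. Cells with zero totals stay all-zero rather
than producing division-by-zero artifacts.

Marker references are read from GMT or two-column (subtype, gene) tables.
The string `"unknown"` is reserved as the classifier's abstention and can
never name a subtype; `"unassigned"` marks cells whose major type had no
registered reference.

## Subtype annotation

**Aggregate marker score.** For each cell and subtype we average the
min–max-scaled log-normalized expression of the subtype's markers. The
scaling maps each gene onto [0, 1] across the dataset (constant genes map
to 0), so the score is bounded, monotone in marker expression, and exactly
0 for a cell expressing no marker — which is what triggers the `"unknown"`
label. The abstention threshold (default 0.01, strict `<`) is exposed
because a literal zero is fragile once expression is normalized.

**Core-cell selection.** Within each labeled subtype we keep the cells at
or above the within-subtype score quantile (default 0.5). Expert atlas
labels are noisy at the boundaries; training on marker-consistent cells
sharpens the per-subtype count profiles. A floor of 20 cells per subtype
(top scorers) protects small subtypes, and subtypes with fewer labeled
cells than the floor are kept whole with a warning.

**Feature selection.** Genes are ranked by the concavity gap
`log(1 + pooled mean) − mean_k log(1 + subtype-k mean)`, which is zero iff
the subtype means coincide and grows with between-subtype heterogeneity
(Jensen's inequality guarantees non-negativity). It is deterministic,
cheap, and count-scale. The default keeps 200 genes per fold; feature
selection is re-run inside every cross-validation fold so no information
leaks from the held-out fifth.

**Template estimation and classification.** With `G` the union of prior
markers and selected genes, each subtype's gene probabilities are
Laplace-smoothed multinomial estimates over its core cells
(`p_ij = (n_ij + 1) / (N_j + |G|)`), so columns sum to one and no
probability is exactly zero. Markers carry a weight
`w_i = 1 + log(1 + score_i)` where `score_i` is the mean scaled expression
of marker `i` over the core cells of the subtype(s) it marks, capped to
[0, 1] so weights live in [1, 1 + log 2]; non-markers have `w_i = 1`
exactly. A cell is assigned `argmax_j Σ_i x_i log(w_i p_ij)`; ties break to
the earliest subtype in template order for determinism, and a cell with
zero counts on all template genes is `"unknown"` (all likelihoods equal).
Because the weights are per-gene, not per-subtype, they reweight the
evidence per transcript without ever flipping a comparison on their own —
a property the tests assert.

**Cross-validation and voting.** Training uses a stratified 5-fold split
(4:1) under an explicit seed; per-fold accuracy and Cohen's kappa are
computed on the held-out fifth with abstentions excluded from numerator and
denominator. Annotation of new data classifies with all five fold models
and votes: a label needs at least 3 of 5 votes (abstentions never count),
otherwise the cell is `"unknown"`. Whether folds should share one feature
selection was genuinely open; re-selecting per fold is the conservative
choice (slightly pessimistic CV metrics, no leakage).

## Label similarity maps

Each reference model assigns each cell one label, giving label–cell sets
per (reference, subtype); `"unknown"`/`"unassigned"` cells appear in no set
because abstention is not a subtype. The similarity of two labels is the
Jaccard index of their cell sets; within one reference the sets partition
the labeled cells, so within-reference off-diagonals are exactly zero and
non-empty labels have unit self-similarity. Per-dataset matrices are
integrated by elementwise mean and population variance (the datasets are a
fixed collection, not a sample), with label pairs a dataset never produced
excluded from both moments rather than zero-filled — zero-filling only
happens, with a warning, when the clustering and embedding steps need a
complete matrix. Hierarchical clustering uses average linkage on `1 − J`
(a similarity-map convention that is robust to outlier labels), serialized
to Newick so trees diff cleanly; the embedding is classical (Torgerson)
MDS with a sign convention (first nonzero loading positive per axis) to
make coordinates reproducible.

## Malignancy classification

The feature scheme is the package's contribution here; the DE engine is
not. `rank_de_genes_bulk()` ranks genes per cancer type by
|log2 fold change| of mean `log2(1 + x)` expression tumor vs normal and is
pluggable (`rank_fun`) for moderated statistics. Genes appearing in
strictly more than `min_occurrence` per-type lists (default 8 — a gene
must recur in at least 9 types) form the bulk feature set; after
restriction to the single-cell gene universe they are united with the
top-variance single-cell genes (default 2000). The classifier is an
XGBoost boosted-tree ensemble with a binary logistic objective and fixed,
recorded hyperparameters (depth 6, 200 rounds, learning rate 0.1, one
thread); the 0.5 probability cutoff for the binary call is configurable.
Train/validation splits assign whole samples to one side — cells of one
biopsy are strongly correlated, and random cell-level splits would
overstate generalization; the split re-draws (up to 100 seeds) until both
sides contain both classes. Evaluation reports the confusion matrix,
accuracy, and the Mann–Whitney (rank-based, tie-averaged) AUC, which the
tests pin to brute-force concordant-pair counting.

## Spatial analysis

**Geometry.** The neighbor rule — spots closer than 1.5 × the minimum
nonzero spot distance — yields the six direct neighbors on a regular hex
lattice and four on a square lattice, without hard-coding a platform.
Morphology QC drops connected tissue components below a size floor and
spots with extreme low UMI/gene counts, then rebuilds the graph.

**Boundaries and ligand–receptor testing.** A spot of either cluster is a
boundary spot when any neighbor belongs to the other cluster; connected
boundary components under 20 spots are discarded so permutation tests have
data to work with. Interaction strength is the mean of the ligand's
average log-normalized expression in one cluster and the receptor's in the
other (directional, CellPhoneDB-style). Significance shuffles the cluster
labels among the two clusters' spots (the label-exchangeability null
within the pair; shuffling across the whole slide would conflate cluster
identity with location) and counts the proportion of null strengths
strictly greater than the observed one. Ties therefore do not count as
exceeding; a degenerate all-tie null yields p = 0 and is caught by the
companion strength filter (p < .05 **and** strength at or above the median
across tested pairs, both configurable).

**Moran statistics.** Spatial weights are `1/d²`, cut at 2.5 × the minimum
spot distance, symmetric with zero diagonal. Global Moran's I is

> GMI = (n / S0) · Σ_ij w_ij z_i z_j / Σ_i z_i², z = x − x̄,

and samples with GMI > 0.5 (configurable, bypassable) are considered to
carry distinct spatial structure. Local Moran's I is reported with the
per-spot normalization `S_i² = Σ_{j≠i} z_j² / (n − 1)` — note this is a
sum of squares about the *global* mean, implemented verbatim even though
some textbook variants differ. The global and local statistics satisfy an
exact identity, `GMI = Σ_i LMI_i S_i² / (S0 · m2)` with `m2 = Σ z²/n`,
which the tests assert.

**Significance of local Moran's I.** P-values come from the conditional
randomization null: hold the spot's own value, permute the remaining
scores over the other spots. For the `m2`-standardized statistic the first
two moments of that permutation distribution are exact in closed form (a
weighted sum of exchangeable values), leaving the normal approximation as
the only approximation. We chose the conditional scheme over
total-randomization moments after measuring both on Gaussian-null grids
(500 spots, 200 replicates): the total-randomization z-test ran slightly
conservative (empirical level ≈ 0.047 at nominal 0.05) while the
conditional test is within sampling error of nominal. A seeded conditional
permutation fallback (`n_perm`) verifies the analytic route. Spots with no
neighbor inside the weight cutoff get p = 1 with a warning. When
calibration is assessed, the replicate — not the spot — is the independent
sampling unit, because all spots of one map share the same score draw.

**Structure calling.** Strategy `"fdr"` applies Benjamini–Hochberg to the
local Moran p-values and calls spots with adjusted p < .05 whose signature
score also exceeds the median — the second condition is what keeps the
false-call rate low on the cold side of a structure. Strategy `"zscore"`
restricts to raw p < .05, re-standardizes the signature scores within that
candidate set, and calls spots whose new one-sided p < .05; by
construction only the upper tail of candidates survives, so this strategy
is far stricter and suits slides where the FDR route over-calls.

## Synthetic data

The generators produce every input with known truth under a single seed:
negative-binomial counts (dispersion 0.5) with disjoint marker blocks and
a fold-change dial for subtypes; log-normal bulk cohorts (14 cancer types,
10 tumor + 10 normal each by default) with a 30-gene shared core planted
in 10 types plus per-type private genes; hexagonal lattices with unit
spacing (so the 1.5 and 2.5 distance rules are exercised at known values),
a two-cluster split, a planted disk, and a ligand/receptor pair elevated
on opposite sides. The disk elevation is specified in background-score
standard deviations and calibrated iteratively on the score scale, because
scaling counts inflates the library size and `log1p` saturates — a single
pass delivers only about two-thirds of the requested shift. The problem
sizes used by the test suite (up to 2000 cells × 500 genes, 30 × 30
lattices, 200-replicate calibrations) were chosen as the smallest scales
at which the planted effects and null calibrations are statistically
unambiguous.

What the generators do *not* emulate: batch effects, ambient RNA,
doublets, gene–gene correlation beyond the planted blocks, irregular
tissue shapes, or platform-specific noise. Passing tests therefore
demonstrate correctness of the algorithms and their statistical
calibration under clean conditions — not robustness to real-data artifacts
such as atlas label noise or cross-study batch structure.

## Degenerate inputs and numerical conventions

Constant signature scores are refused by the Moran statistics ("no spatial
variance") rather than returning 0/0; constant genes min-max-scale to 0;
empty label-set pairs get similarity 0 with a warning; missing template or
model genes are treated as zero counts (with a warning when more than half
are missing, and a hard error for the malignancy model below 50%
coverage); classification ties break to template order; all stochastic
steps (folds, splits, permutations, control-gene draws, generators) take
explicit seeds and are bit-reproducible.

## Known limitations

- The multinomial classifier assumes transcripts are exchangeable given
  the subtype; strong technical covariates (cell size, chemistry) are not
  modeled and should be handled upstream.
- Similarity maps inherit any systematic annotation bias: two references
  that both mislabel a population will agree confidently.
- The malignancy classifier is only as pan-cancer as its training cohort;
  the sample-wise split measures cross-sample, not cross-platform,
  generalization.
- The normal approximation behind the local Moran z-scores thins out for
  spots with very few neighbors; the permutation fallback is the reference
  in that regime.
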