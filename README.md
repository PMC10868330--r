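# tmescope

Tools for dissecting the tumor microenvironment (TME) in single-cell and
spatial transcriptomics data, aimed at computational biologists who need to
(1) transfer expert cell-subtype annotations from published tumor atlases to
new scRNA-seq datasets, (2) quantify how subtype labels defined by different
studies relate to each other, (3) call malignant cells without an internal
copy-number reference, and (4) locate spatially coherent structures
(tertiary lymphoid structures, capsules, interaction boundaries) on spatial
transcriptomics slides.

## Methods at a glance

**Subtype annotation.** A reference atlas with subtype labels *L* and
curated markers *G*<sub>prior</sub> trains one template per stratified
cross-validation fold. Core training cells are picked by an aggregate marker
score (mean of min–max-scaled log-normalized marker expression, bounded in
[0, 1]); features are the union of *G*<sub>prior</sub> and the genes with
the largest entropy gap Δ*S*<sub>g</sub> = log(1 + μ̄) − mean<sub>k</sub>
log(1 + μ<sub>k</sub>) between pooled and per-subtype means. Each subtype's
gene probabilities *p*<sub>ij</sub> are Laplace-smoothed multinomial
estimates on core-cell counts, and a new cell with count vector *x* is
assigned

> ĵ = argmax<sub>j</sub> Σ<sub>i</sub> x<sub>i</sub> log(w<sub>i</sub> p<sub>ij</sub>),  w<sub>i</sub> = 1 + 1[i ∈ G<sub>prior</sub>] · log(1 + score<sub>i</sub>)

with cells expressing no prior marker labeled `"unknown"`. The five fold
models vote; a label needs ≥ 3 of 5 votes, otherwise `"unknown"`.

**Label similarity maps.** Applying every reference model to every dataset
yields label–cell sets *C*<sub>ij</sub>; every pair of labels gets the
Jaccard similarity |C<sub>a</sub> ∩ C<sub>b</sub>| / |C<sub>a</sub> ∪
C<sub>b</sub>| and per-dataset matrices are integrated by elementwise mean
(J) and population variance (V), then summarized by average-linkage
hierarchical clustering on 1 − J and classical MDS.

**Malignancy classification.** Features are the union of genes recurrently
differential (strictly more than 8 of 14 cancer types by default) in bulk
tumor-vs-normal contrasts, restricted to the single-cell gene universe, and
the top-variance single-cell genes; an XGBoost binary-logistic classifier is
trained with sample-wise train/validation splits and evaluated by confusion
matrix, accuracy, and rank-based AUC.

**Spatial TME analysis.** Spots closer than 1.5·min(d) are neighbors (six
on a Visium-style hex lattice). Boundary spots between two clusters are
those with a neighbor of the other cluster; connected boundary components
under 20 spots are discarded. Ligand–receptor strength between clusters is
the mean of the ligand's and receptor's cluster-average expression, with
significance from 1000 label shuffles. Signature scores feed global Moran's
I with weights w<sub>ij</sub> = 1/d<sub>ij</sub>² cut at 2.5·min(d); samples
with GMI > 0.5 are scanned spot-by-spot with local Moran's I, standardized
by exact conditional-randomization moments, and structures are called either
by BH-adjusted p < .05 plus score-above-median, or by re-z-scoring within
the raw-significant region.

Seeded synthetic generators (`simulate_subtype_dataset()`,
`simulate_bulk_cohort()`, `simulate_malignancy_dataset()`,
`simulate_spatial_sample()`) produce every input with planted ground truth.

## Worked example

```r
library(tmescope)

# 1. annotation: train a five-fold ensemble on a synthetic reference
sim <- simulate_subtype_dataset(n_cells = 1000, n_genes = 300, seed = 1)
ens <- train_cv_ensemble(sim$dataset, sim$labels, sim$ref,
                         n_genes = 100, seed = 0, name = "refA")
glance(ens)
#>   mean_accuracy var_accuracy mean_kappa var_kappa n_folds
#> 1             1            0          1         0       5
annotate_cells(sim$dataset, ens)
#> <annotation_result> 1000 cells
#> alpha  beta gamma
#>   333   334   333

# 2. spatial structures: a planted signature disk on a 30 x 30 hex lattice
sp  <- simulate_spatial_sample(rows = 30, cols = 30, seed = 0)
sc  <- score_signature(sp$grid, sp$signature)
global_morans_i(sp$grid, sc)
#> [1] 0.541                      # > 0.5: the sample has spatial structure
call <- call_structures(sp$grid, sc, strategy = "fdr")
#> <structure_call> GMI 0.541 (fdr strategy): 196 of 900 spots in structure
mean(call$in_structure[sp$structure_mask])    # 0.908 of the disk recovered
mean(call$in_structure[!sp$structure_mask])   # 0.013 background call rate
```

The cross-validated accuracy/kappa of 1 reflect the fold-change-50 planted
markers (the generator's well-separated regime); the structure call
recovers 90.8% of the planted disk while flagging 1.3% of background
spots. `plot_spots(sp$grid, call)` draws the called structure;
`autoplot(simmap)` renders similarity-map heatmaps and MDS embeddings.

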