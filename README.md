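# mucocensus

Consensus-clustering stability census and marker analysis for airway
epithelium scRNA-seq.

During regeneration of the human airway epithelium, basal cells give rise
to suprabasal, club, goblet (secretory) and multiciliated cells along a
branching differentiation trajectory, with rare double-positive
intermediates (e.g. MUC5AC+/FOXJ1+ cells) linking the secretory and
multiciliated fates. Analyzing such data requires knowing *how much to
trust a clustering*: which cell populations are robust to perturbation,
which cells sit between populations, and which marker genes are stable
under resampling. `mucocensus` implements that toolbox as a tested R
package:

- **Stability census** — for each candidate number of clusters
  *k* ∈ {2,…,9}, cluster 10 random 90%-subsets of the cells 10 times
  each; accumulate the cell-by-cell co-clustering frequency matrix
  *S*ᵢⱼ = (runs clustering *i*,*j* together)/(runs with both present);
  cut an average-linkage consensus on the Euclidean distances between
  rows of *S*; choose *k* at the elbow of the average intra-cluster
  stability curve; flag cells with per-cell stability < 70% as
  *unassigned*. The base clusterer (default: log1p → 30 PCs → k-means) is
  pluggable.
- **QC & normalization** — percentile-based cell filters (features,
  dropout, library size, mitochondrial fraction), ≥ 5-cell gene
  detection filter, two-pass median-ratio normalization, binned-dispersion
  highly variable gene selection.
- **Markers** — one-vs-all Wilcoxon rank-sum tests (exact for small
  samples) with BH FDR; a pooled robustness design (10 × 100-cell pools
  vs balanced mixtures) compared by rank–rank hypergeometric overlap.
- **Annotation** — marker-set mean expression z-scored across cells; the
  top-scoring type annotates each cell, modal vote annotates clusters.
- **Hybrids & smoothing** — double-positive cell fractions with exact
  Clopper–Pearson CIs under "detected" or top-50-percentile positivity;
  heatmap-style smoothing (per-gene z-scores averaged over 10 neighboring
  cells, ordered by branch → cluster emergence → pseudotime).
- **Simulator** — negative-binomial branching-lineage generator
  (cycling basal → basal → suprabasal → club → {goblet, deuterosomal →
  multiciliated}) with planted markers, mitochondrial genes, library-size
  variation and hybrid cells, exposing full ground truth.

## Worked example

```r
library(mucocensus)

sim  <- sim_airway_standard(n_cells = 600, seed = 42)   # planted truth
norm <- normalize_counts(filter_genes(sim$matrix))
expr <- as.matrix(norm$values[select_hvg(norm, 300), ])
res  <- run_census(expr, perturbation_plan(k_range = 2:9, seed = 11))
print(res)
```

```
Consensus census: selected k = 6; 1/600 cells unassigned (< 70% stability)
 k     intra       inter
 2 0.9041514 0.133158047
 3 0.9335383 0.052522262
 4 0.9356493 0.058281104
 5 0.9319855 0.032597164
 6 0.9869764 0.004835198
 7 0.9510618 0.006353517
 8 0.9246749 0.009941385
 9 0.9275543 0.011347289
```

The intra-stability curve peaks sharply at k = 6 — the six planted cell
types — where within-cluster pairs co-cluster in 98.7% of perturbed runs
and between-cluster pairs in 0.5%. The consensus labels recover the
planted types with ARI 0.93 (`mclust::adjustedRandIndex(res$labels,
sim$truth$cell_type)`), and the one unassigned cell is a cell whose
membership genuinely flips across runs.

Quantifying planted hybrid (double-positive) cells:

```r
sim <- sim_secretory_mcc_compartment(n_cells = 1000,
                                     hybrid_fraction = 0.089, seed = 3)
norm <- normalize_counts(sim$matrix)
double_positive_fraction(norm, sim$marker_sets$goblet[1],
                         sim$marker_sets$multiciliated[1],
                         rule = "detected", denominator = "either")
```

```
$fraction
[1] 0.0810537

$ci
[1] 0.06479113 0.09986484

$n_double
[1] 80

$n_denominator
[1] 987
```

89 hybrids were planted among 1,000 goblet/multiciliated cells; the
measured 8.1% (CI 6.5–10.0%) — 80 double-positive of 987 flag-positive
cells — recovers the planted 8.9% within its exact binomial interval (the
small deficit is negative-binomial dropout of the flag genes).

## Analysis workflow

`analysis/01_simulate.R` … `analysis/06_hybrids_smoothing.R` run the full
study pipeline as numbered scripts — simulate, QC + normalize, census,
markers + RRHO, annotate, hybrids + smoothing — each printing what it
found and writing its tables under `results/`.

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

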