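Package: mucocensus
Title: Consensus-Clustering Stability Census and Marker Analysis for
    Airway Epithelium scRNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for perturbation-based consensus clustering
    of single-cell RNA-seq UMI count data, built around a clustering
    stability census for charting mucociliary differentiation of the
    human airway epithelium. Repeated clustering of randomly subsampled
    cells yields a cell-by-cell co-clustering frequency ("stability")
    matrix; hierarchical consensus partitions, intra-/inter-cluster
    stability curves for choosing the number of clusters, and per-cell
    stability scores for flagging unassigned cells are derived from it.
    The package also provides per-cell quality-control filtering and
    two-pass median-ratio normalization, one-vs-all Wilcoxon rank-sum
    marker detection with pooled-cell robustness replicates compared by
    rank-rank hypergeometric overlap, marker z-score cell-type
    annotation, double-positive (hybrid) cell quantification with exact
    binomial confidence intervals, pseudotime-ordered expression
    smoothing, and a negative-binomial simulator of branching airway
    differentiation (basal to secretory and multiciliated lineages) with
    planted ground truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
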