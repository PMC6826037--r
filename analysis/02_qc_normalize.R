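#!/usr/bin/env Rscript
# Step 2 — quality control and normalization.
#
# Computes per-cell QC metrics, applies the distribution-relative filters
# (cells outside the 5th-95th percentile of expressed features, dropout
# and library size; cells above the 95th percentile of mitochondrial
# fraction), keeps genes detected in >= 5 cells, normalizes by the
# median-library scaling, and selects highly variable genes by binned
# dispersion. Writes the QC table, filter report and HVG list.

suppressPackageStartupMessages(library(mucocensus))

mat <- read_10x_triplet("results/counts_10x")
qc <- compute_qc(mat)
filt <- filter_cells(mat, qc)
cat("cell filter removed", nrow(filt$report$removed_cells), "of",
    ncol(mat$values), "cells\n")
print(table(unlist(strsplit(filt$report$removed_cells$reasons, ","))))

genes_kept <- filter_genes(filt$matrix)
cat("gene filter kept", nrow(genes_kept$values), "of",
    nrow(filt$matrix$values), "genes (>= 1 UMI in >= 5 cells)\n")

norm <- normalize_counts(genes_kept)
hvg <- select_hvg(norm, n_top = 300)
cat("selected", length(hvg), "highly variable genes\n")

write_dense_tsv(norm, "results/normalized.tsv")
write_tables(list(
  qc_metrics = qc,
  removed_cells = filt$report$removed_cells,
  hvg = data.frame(gene = names(hvg), rank = seq_along(hvg))),
  "results")
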