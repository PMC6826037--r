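#' Compute per-cell quality-control metrics
#'
#' For each cell: the number of expressed features (genes with at least one
#' UMI), the dropout percentage (fraction of genes with zero counts, equal
#' to 1 - n_features / n_genes), the library size (total UMI count) and the
#' fraction of UMIs mapping to mitochondrial genes.
#'
#' @param mat a raw-layer \code{CountMatrix}.
#' @return A data frame with one row per cell: \code{barcode},
#'   \code{n_features}, \code{dropout_pct}, \code{library_size},
#'   \code{mito_pct}.
#' @export
compute_qc <- function(mat) {
  stopifnot(inherits(mat, "CountMatrix"))
  if (nrow(mat$values) == 0L || ncol(mat$values) == 0L)
    stop("empty matrix")
  if (mat$layer != "raw") stop("QC metrics are defined on the raw layer")
  v <- mat$values
  n_features <- Matrix::colSums(v > 0)
  library_size <- Matrix::colSums(v)
  mito_umi <- if (any(mat$is_mito))
    Matrix::colSums(v[mat$is_mito, , drop = FALSE]) else 0
  data.frame(barcode = mat$barcodes,
             n_features = as.integer(n_features),
             dropout_pct = 1 - n_features / nrow(v),
             library_size = library_size,
             mito_pct = ifelse(library_size > 0, mito_umi / library_size, 0))
}

#' Filter cells on distribution-relative QC thresholds
#'
#' Removes cells strictly below the 5th or strictly above the 95th
#' empirical percentile (linear-interpolation quantiles) of the number of
#' expressed features, the dropout percentage and the library size, and
#' cells strictly above the 95th percentile of mitochondrial fraction.
#' Thresholds are computed jointly on the unfiltered distributions; a cell
#' may be removed for several reasons, all of which are reported. Strict
#' inequalities mean a fully tied metric removes nobody.
#'
#' @param mat a raw-layer \code{CountMatrix}.
#' @param metrics QC table from \code{\link{compute_qc}} on \code{mat}.
#' @param lower,upper percentile bounds (defaults 0.05 and 0.95).
#' @return A list: \code{matrix} (filtered \code{CountMatrix}) and
#'   \code{report} (a \code{FilterReport} list with \code{kept_cells},
#'   \code{removed_cells} — a data frame of barcode and comma-separated
#'   reason codes — and the \code{thresholds} actually applied).
#' @export
filter_cells <- function(mat, metrics, lower = 0.05, upper = 0.95) {
  stopifnot(inherits(mat, "CountMatrix"))
  if (!identical(metrics$barcode, mat$barcodes))
    stop("metrics were not computed on this matrix")
  n <- ncol(mat$values)
  if (n < 20L) warning("fewer than 20 cells; distribution-relative QC ",
                       "thresholds are unreliable")
  q <- function(x, p) stats::quantile(x, p, names = FALSE, type = 7)
  thr <- list(
    feat = q(metrics$n_features, c(lower, upper)),
    dropout = q(metrics$dropout_pct, c(lower, upper)),
    libsize = q(metrics$library_size, c(lower, upper)),
    mito_high = q(metrics$mito_pct, upper))
  reasons <- list(
    feat_low = metrics$n_features < thr$feat[1L],
    feat_high = metrics$n_features > thr$feat[2L],
    dropout_low = metrics$dropout_pct < thr$dropout[1L],
    dropout_high = metrics$dropout_pct > thr$dropout[2L],
    libsize_low = metrics$library_size < thr$libsize[1L],
    libsize_high = metrics$library_size > thr$libsize[2L],
    mito_high = metrics$mito_pct > thr$mito_high)
  remove <- Reduce(`|`, reasons)
  reason_str <- vapply(seq_len(n), function(i)
    paste(names(reasons)[vapply(reasons, `[`, logical(1), i)], collapse = ","),
    character(1))
  report <- list(
    kept_cells = mat$barcodes[!remove],
    removed_cells = data.frame(barcode = mat$barcodes[remove],
                               reasons = reason_str[remove]),
    thresholds = thr)
  list(matrix = subset_matrix(mat, cells = which(!remove)), report = report)
}

#' Filter genes on minimum detection
#'
#' Keeps genes detected (at least 1 UMI) in at least \code{min_cells}
#' cells. Idempotent.
#'
#' @param mat a raw-layer \code{CountMatrix}.
#' @param min_cells minimum number of cells (default 5).
#' @return The filtered \code{CountMatrix}.
#' @export
filter_genes <- function(mat, min_cells = 5) {
  stopifnot(inherits(mat, "CountMatrix"))
  keep <- Matrix::rowSums(mat$values > 0) >= min_cells
  subset_matrix(mat, genes = which(keep))
}

#' Two-pass median-ratio normalization
#'
#' Pass 1 (unsupervised) scales each cell by its library size divided by
#' the median library size, i.e. the median UMI count acts as the scaling
#' reference. Pass 2 (cluster-guided, run when \code{labels} are supplied)
#' refines each cell's factor against its cluster: the cluster reference is
#' the per-gene mean of pass-1 values over cluster members, the cell's
#' extra factor is the median ratio of cell to reference over pools of
#' expressed genes (genes are pooled into up to 20 expression-ordered bins
#' before taking ratios, because single-gene UMI ratios are dominated by
#' count discreteness; a degenerate zero median falls back to the pass-1
#' factor), and the extra factors are rescaled to mean 1 so the overall
#' scale is untouched. Clusters with fewer than 3 cells fall back
#' to their pass-1 factors (with a message). Normalized value =
#' raw / factor, so within-cell gene rank order is conserved.
#'
#' @param mat a raw-layer \code{CountMatrix}.
#' @param labels optional per-cell cluster labels (second pass).
#' @param log also return the natural-log(1 + x) layer.
#' @return A \code{CountMatrix} with layer \code{"normalized"} (or
#'   \code{"lognorm"} when \code{log = TRUE}); the per-cell scale factors
#'   are attached as attribute \code{"scale_factors"}.
#' @export
normalize_counts <- function(mat, labels = NULL, log = FALSE) {
  stopifnot(inherits(mat, "CountMatrix"))
  if (mat$layer != "raw") stop("normalization starts from the raw layer")
  v <- as.matrix(mat$values)
  libsize <- unname(colSums(v))
  if (any(libsize == 0)) stop("cells with zero total UMI cannot be normalized")
  f1 <- libsize / stats::median(libsize)
  pass1 <- sweep(v, 2L, f1, `/`)
  factor <- f1
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(v) || anyNA(labels))
      stop("every cell must be labeled for the cluster-guided pass")
    f2 <- rep(1, ncol(v))
    for (cl in unique(labels)) {
      members <- which(labels == cl)
      if (length(members) < 3L) {
        message("cluster '", cl, "' has fewer than 3 cells; ",
                "its members keep their pass-1 factors")
        next
      }
      ref <- rowMeans(pass1[, members, drop = FALSE])
      expressed <- which(ref > 0)  # genes carried by the cluster reference
      # pool genes into expression-ordered bins: single-gene UMI ratios are
      # dominated by count discreteness, pooled ratios are not
      n_bins <- max(1L, min(20L, length(expressed) %/% 5L))
      bin <- ceiling(seq_along(expressed) / (length(expressed) / n_bins))
      ord <- expressed[order(ref[expressed])]
      ref_bin <- tapply(ref[ord], bin, sum)
      for (i in members) {
        f <- stats::median(tapply(pass1[ord, i], bin, sum) / ref_bin)
        if (is.finite(f) && f > 0) f2[i] <- f
      }
    }
    f2 <- f2 / mean(f2)
    factor <- f1 * f2
  }
  norm <- sweep(v, 2L, factor, `/`)
  if (log) norm <- log1p(norm)
  out <- count_matrix(norm, mat$gene_ids, mat$barcodes, mat$is_mito,
                      layer = if (log) "lognorm" else "normalized")
  attr(out, "scale_factors") <- factor
  out
}

#' Select highly variable genes by binned expression dispersion
#'
#' Genes are binned into 20 equal-occupancy bins of mean expression;
#' dispersion (variance / mean) is z-scored within each bin, and the
#' \code{n_top} genes with the highest dispersion z-score are returned.
#' Ties are broken deterministically by gene id.
#'
#' @param mat a normalized-layer \code{CountMatrix}.
#' @param n_top number of genes to select (typically 200-500).
#' @param n_bins number of mean-expression bins (default 20).
#' @return Integer vector of selected gene indices (ordered by decreasing
#'   z-score), with gene ids as names.
#' @export
select_hvg <- function(mat, n_top = 300, n_bins = 20) {
  stopifnot(inherits(mat, "CountMatrix"))
  if (mat$layer == "raw")
    stop("select highly variable genes on the normalized layer")
  v <- as.matrix(mat$values)
  if (n_top > nrow(v)) stop("n_top exceeds the number of genes")
  mu <- rowMeans(v)
  va <- apply(v, 1L, stats::var)
  disp <- ifelse(mu > 0, va / mu, 0)
  bin <- ceiling(rank(mu, ties.method = "first") / (length(mu) / n_bins))
  z <- rep(0, length(mu))
  for (b in unique(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, mat$gene_ids)
  sel <- ord[seq_len(n_top)]
  stats::setNames(sel, mat$gene_ids[sel])
}
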