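#' Flag cells positive for a gene
#'
#' Two positivity rules: \code{"detected"} flags cells with any
#' (normalized) expression of the gene; \code{"percentile"} flags cells
#' whose value exceeds the median of the gene's positive (nonzero) cells —
#' the top-50-percentile display rule used for single-gene visualization.
#'
#' @param mat a \code{CountMatrix} or matrix with gene-id rownames.
#' @param gene gene id.
#' @param rule \code{"detected"} (default) or \code{"percentile"}.
#' @return Logical per-cell vector; the threshold actually applied is
#'   attached as attribute \code{"threshold"}.
#' @export
positive_cells <- function(mat, gene, rule = c("detected", "percentile")) {
  rule <- match.arg(rule)
  v <- if (inherits(mat, "CountMatrix")) mat$values else mat
  if (!gene %in% rownames(v)) stop("gene '", gene, "' absent from the matrix")
  vals <- as.numeric(v[gene, ])
  thr <- if (rule == "detected") 0 else {
    pos <- vals[vals > 0]
    if (length(pos)) stats::median(pos) else 0
  }
  structure(vals > thr, threshold = thr)
}

#' Fraction of double-positive (hybrid) cells
#'
#' Quantifies cells positive for both of two genes, with an exact
#' Clopper-Pearson 95\% binomial confidence interval. The default
#' denominator \code{"either"} is the cells positive for at least one of
#' the two genes — the natural reading of "a percentage of the two
#' populations"; \code{"all"} uses every cell; a logical or integer cell
#' subset restricts the computation to those cells first.
#'
#' @param mat a \code{CountMatrix} or matrix.
#' @param gene_a,gene_b the two genes (order does not matter).
#' @param rule positivity rule, see \code{\link{positive_cells}}.
#' @param denominator \code{"either"}, \code{"all"}, or a cell subset
#'   (logical or integer index vector).
#' @param conf confidence level (default 0.95).
#' @return A list: \code{fraction}, \code{ci} (length-2), \code{n_double},
#'   \code{n_denominator}; all \code{NA} (with a message) if the
#'   denominator is empty.
#' @export
double_positive_fraction <- function(mat, gene_a, gene_b,
                                     rule = c("detected", "percentile"),
                                     denominator = "either", conf = 0.95) {
  rule <- match.arg(rule)
  keep <- NULL
  if (!is.character(denominator)) {
    keep <- denominator
    mat <- if (inherits(mat, "CountMatrix")) subset_matrix(mat, cells = which(
      if (is.logical(keep)) keep else seq_len(ncol(mat$values)) %in% keep))
    else mat[, keep, drop = FALSE]
    denominator <- "all"
  }
  pos_a <- positive_cells(mat, gene_a, rule)
  pos_b <- positive_cells(mat, gene_b, rule)
  denom <- switch(denominator,
                  either = which(pos_a | pos_b),
                  all = seq_along(pos_a),
                  stop("unknown denominator mode '", denominator, "'"))
  if (!length(denom)) {
    message("empty denominator: double-positive fraction is undefined")
    return(list(fraction = NA_real_, ci = c(NA_real_, NA_real_),
                n_double = 0L, n_denominator = 0L))
  }
  k <- sum(pos_a[denom] & pos_b[denom])
  n <- length(denom)
  list(fraction = k / n, ci = clopper_pearson(k, n, conf),
       n_double = k, n_denominator = n)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k successes; @param n trials; @param conf confidence level.
#' @return Length-2 numeric vector (lower, upper).
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo, hi)
}

#' Order cells by branch, cluster emergence, then pseudotime
#'
#' The heatmap ordering rule: cells are sorted by branch label, within a
#' branch by their cluster's emergence rank (the rank of the cluster's
#' median pseudotime), and within a cluster by pseudotime; remaining ties
#' break by barcode, and the sort is stable.
#'
#' @param pseudotime per-cell pseudotime (no missing values).
#' @param branch per-cell branch labels (ordering follows
#'   \code{sort(unique(branch))} unless \code{branch} is a factor, whose
#'   level order is respected).
#' @param cluster_labels per-cell cluster labels.
#' @param barcodes optional per-cell barcodes for the final tie-break.
#' @return Integer permutation of the cells.
#' @export
order_cells <- function(pseudotime, branch, cluster_labels, barcodes = NULL) {
  n <- length(pseudotime)
  stopifnot(length(branch) == n, length(cluster_labels) == n)
  if (anyNA(pseudotime))
    stop("missing pseudotime for cells: ",
         paste(utils::head(which(is.na(pseudotime)), 5L), collapse = ", "))
  if (is.null(barcodes)) barcodes <- sprintf("%09d", seq_len(n))
  branch_rank <- if (is.factor(branch)) as.integer(branch)
                 else match(branch, sort(unique(branch)))
  med <- tapply(pseudotime, cluster_labels, stats::median)
  emergence <- rank(med, ties.method = "first")[as.character(cluster_labels)]
  order(branch_rank, emergence, pseudotime, barcodes)
}

#' Z-score and smooth expression along an ordering
#'
#' Each gene is z-scored across all cells (population standard deviation,
#' denominator n; zero-variance genes are set to 0 and flagged), then
#' smoothed by a centered moving average of width \code{window} along the
#' given cell ordering, truncating the window symmetrically at segment
#' ends. When \code{branch} is supplied, smoothing is applied within each
#' branch's contiguous segment of the ordering independently, so branch
#' boundaries do not bleed into each other.
#'
#' @param mat a \code{CountMatrix} or matrix (normalized values).
#' @param ordering integer permutation of the cells (from
#'   \code{\link{order_cells}}).
#' @param window moving-average width in cells (default 10, the
#'   heatmap-smoothing window).
#' @param branch optional per-cell branch labels (in original cell order).
#' @return An \code{OrderedExpression} list: \code{smoothed} (genes x
#'   cells, columns in \code{ordering}), \code{ordering}, \code{window},
#'   \code{zero_variance} (flagged gene ids).
#' @export
smooth_expression <- function(mat, ordering, window = 10, branch = NULL) {
  v <- if (inherits(mat, "CountMatrix")) as.matrix(mat$values) else as.matrix(mat)
  n <- ncol(v)
  stopifnot(length(ordering) == n, !anyDuplicated(ordering), window >= 1)
  if (window > n) stop("window (", window, ") exceeds the number of cells")
  mu <- rowMeans(v)
  sd_pop <- sqrt(rowMeans((v - mu)^2))
  zero_var <- sd_pop == 0
  z <- (v - mu) / ifelse(zero_var, 1, sd_pop)
  z[zero_var, ] <- 0
  z <- z[, ordering, drop = FALSE]
  segments <- if (is.null(branch)) list(seq_len(n)) else {
    b <- as.character(branch)[ordering]
    split(seq_len(n), cumsum(c(TRUE, b[-1L] != b[-n])))
  }
  half <- (window - 1) %/% 2
  smoothed <- z
  for (seg in segments) {
    m <- length(seg)
    for (j in seq_len(m)) {
      # centered window, truncated symmetrically at the segment ends
      h <- min(half, j - 1L, m - j)
      w <- seg[(j - h):(j + h)]
      if (window %% 2 == 0 && j + h + 1L <= m && h == half)
        w <- c(w, seg[j + h + 1L])  # even windows extend one cell forward
      smoothed[, seg[j]] <- rowMeans(z[, w, drop = FALSE])
    }
  }
  structure(list(smoothed = smoothed, ordering = ordering, window = window,
                 zero_variance = rownames(v)[zero_var] %||%
                   which(zero_var)),
            class = "OrderedExpression")
}
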