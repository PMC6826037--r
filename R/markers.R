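#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of location shift between two samples. For small
#' tie-free inputs (n1 + n2 <= 12) the exact null distribution of the
#' Mann-Whitney U statistic is used; otherwise the normal approximation
#' with the standard tie-correction of the variance and a 0.5 continuity
#' correction.
#'
#' @param x,y numeric samples (both non-empty).
#' @return A list with \code{U} (the rank-sum statistic for \code{x},
#'   shifted to the Mann-Whitney form), \code{p} (two-sided p-value) and
#'   \code{exact} (whether the exact distribution was used).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  all_vals <- c(x, y)
  r <- rank(all_vals)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_vals)
  has_ties <- any(ties > 1L)
  if (length(unique(all_vals)) == 1L)
    return(list(U = U, p = 1, exact = FALSE))
  if (!has_ties && n1 + n2 <= 12L) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    return(list(U = U, p = p, exact = TRUE))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, exact = FALSE))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

# vectorized one-vs-rest Mann-Whitney over the genes of a matrix
# (normal approximation with tie and continuity corrections, the same
# formulas as wilcoxon_rank_sum's large-sample path)
wilcox_one_vs_rest <- function(v, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  mu <- n1 * n2 / 2
  res <- t(apply(v, 1L, function(vals) {
    r <- rank(vals)
    U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(vals)
    if (length(ties) == 1L) return(c(U, 1))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    c(U, min(1, 2 * stats::pnorm(-abs(z))))
  }))
  list(U = res[, 1L], p = res[, 2L])
}

#' One-vs-all marker detection for every cluster
#'
#' For each cluster, every gene passing the detection prefilter is tested
#' cluster-vs-rest with the Wilcoxon rank-sum test; log fold changes use
#' natural log with pseudocount 1 on mean normalized expression, and
#' Benjamini-Hochberg FDR is computed within each cluster over its tested
#' genes.
#'
#' @param mat a normalized-layer \code{CountMatrix} (or bare matrix).
#' @param labels per-cell cluster labels (>= 2 clusters).
#' @param min_pct minimum detection fraction in either group for a gene to
#'   be tested (default 0.1).
#' @return A \code{MarkerTable} data frame with columns \code{cluster},
#'   \code{gene}, \code{mean_in}, \code{mean_out}, \code{log_fc},
#'   \code{pct_in}, \code{pct_out}, \code{U}, \code{p}, \code{fdr}, sorted
#'   by (cluster, fdr, -|log_fc|).
#' @export
find_all_markers <- function(mat, labels, min_pct = 0.1) {
  v <- if (inherits(mat, "CountMatrix")) as.matrix(mat$values) else as.matrix(mat)
  gene_ids <- rownames(v) %||% sprintf("gene%d", seq_len(nrow(v)))
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(v))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stop("need at least 2 clusters for one-vs-all tests")
  out <- list()
  for (cl in clusters) {
    in_group <- labels == cl
    if (sum(in_group) < 3L) {
      warning("cluster '", cl, "' has fewer than 3 cells; skipped")
      next
    }
    pct_in <- rowMeans(v[, in_group, drop = FALSE] > 0)
    pct_out <- rowMeans(v[, !in_group, drop = FALSE] > 0)
    tested <- which(pmax(pct_in, pct_out) >= min_pct)
    if (!length(tested)) next
    w <- wilcox_one_vs_rest(v[tested, , drop = FALSE], in_group)
    mean_in <- rowMeans(v[tested, in_group, drop = FALSE])
    mean_out <- rowMeans(v[tested, !in_group, drop = FALSE])
    tab <- data.frame(cluster = cl, gene = gene_ids[tested],
                      mean_in = mean_in, mean_out = mean_out,
                      log_fc = log(mean_in + 1) - log(mean_out + 1),
                      pct_in = pct_in[tested], pct_out = pct_out[tested],
                      U = w$U, p = w$p,
                      fdr = stats::p.adjust(w$p, method = "BH"))
    out[[cl]] <- tab[order(tab$fdr, -abs(tab$log_fc)), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled-cell differential-expression robustness replicates
#'
#' Repeats a pooled differential comparison \code{reps} times: each
#' repetition samples \code{pool_size} cells from the target cluster and,
#' in one-vs-all mode, \code{pool_size} cells as an equal mixture of all
#' other clusters (balanced across clusters, remainder distributed
#' round-robin in cluster-label order); in one-vs-one mode, a same-size
#' pool from the reference cluster. Each repetition yields a ranked marker
#' table; ranking robustness across repetitions can then be assessed with
#' \code{\link{rrho}}.
#'
#' @param mat normalized \code{CountMatrix} or matrix.
#' @param labels per-cell cluster labels.
#' @param target target cluster label.
#' @param reference for mode \code{"one_vs_one"}, the comparison cluster.
#' @param pool_size cells per pool (default 100).
#' @param reps repetitions (default 10).
#' @param seed RNG seed; repetition r uses a seed derived from it.
#' @param mode \code{"one_vs_all"} or \code{"one_vs_one"}.
#' @return List of \code{reps} marker tables (columns as in
#'   \code{\link{find_all_markers}}, cluster = target), each sorted by
#'   (fdr, -|log_fc|).
#' @export
pooled_de <- function(mat, labels, target, reference = NULL, pool_size = 100,
                      reps = 10, seed = 1,
                      mode = c("one_vs_all", "one_vs_one")) {
  mode <- match.arg(mode)
  v <- if (inherits(mat, "CountMatrix")) as.matrix(mat$values) else as.matrix(mat)
  gene_ids <- rownames(v) %||% sprintf("gene%d", seq_len(nrow(v)))
  labels <- as.character(labels)
  target_cells <- which(labels == target)
  if (length(target_cells) < pool_size)
    stop("target cluster '", target, "' has ", length(target_cells),
         " cells; pool_size = ", pool_size, " required")
  if (mode == "one_vs_one") {
    if (is.null(reference)) stop("one_vs_one mode needs a reference cluster")
    other_groups <- list(which(labels == reference))
    names(other_groups) <- reference
  } else {
    others <- sort(setdiff(unique(labels), target))
    other_groups <- lapply(others, function(cl) which(labels == cl))
    names(other_groups) <- others
  }
  quota <- pool_quota(pool_size, lengths(other_groups))
  lapply(seq_len(reps), function(r) {
    set.seed(derive_seed(seed, r))
    pool_in <- sample(target_cells, pool_size)
    pool_out <- unlist(lapply(seq_along(other_groups), function(i)
      sample(other_groups[[i]], quota[i])), use.names = FALSE)
    w <- t(apply(v, 1L, function(vals) {
      res <- wilcoxon_rank_sum(vals[pool_in], vals[pool_out])
      c(res$U, res$p)
    }))
    mean_in <- rowMeans(v[, pool_in, drop = FALSE])
    mean_out <- rowMeans(v[, pool_out, drop = FALSE])
    tab <- data.frame(cluster = target, gene = gene_ids,
                      mean_in = mean_in, mean_out = mean_out,
                      log_fc = log(mean_in + 1) - log(mean_out + 1),
                      pct_in = rowMeans(v[, pool_in, drop = FALSE] > 0),
                      pct_out = rowMeans(v[, pool_out, drop = FALSE] > 0),
                      U = w[, 1L], p = w[, 2L],
                      fdr = stats::p.adjust(w[, 2L], method = "BH"))
    tab <- tab[order(tab$fdr, -abs(tab$log_fc)), ]
    rownames(tab) <- NULL
    tab
  })
}

# balanced mixture quota with round-robin remainder, in group order
pool_quota <- function(pool_size, sizes) {
  m <- length(sizes)
  quota <- rep(as.integer(pool_size %/% m), m)
  extra <- pool_size %% m
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  if (any(quota > sizes))
    stop("insufficient cells for an equal mixture: need ",
         paste(quota, collapse = "/"), " from clusters of size ",
         paste(sizes, collapse = "/"))
  quota
}

#' Rank-rank hypergeometric overlap of two ranked gene lists
#'
#' For every pair of rank thresholds (i, j) on a step grid, counts the
#' overlap k between the top-i genes of list a and the top-j genes of list
#' b and records -log10 of the hypergeometric upper-tail probability
#' P[X >= k] with population N, i successes and j draws. Large agreement
#' between the heads of the two rankings yields large map entries.
#'
#' @param ranked_a,ranked_b character vectors: permutations of the same
#'   gene universe, best-ranked first.
#' @param step grid step (default \code{max(1, N \%/\% 50)}).
#' @param clip upper clip for map entries (default 320).
#' @return An \code{RRHOMap} list: \code{map} (matrix of -log10 tail
#'   probabilities with threshold dimnames), \code{thresholds},
#'   \code{step}, \code{universe_size}.
#' @export
rrho <- function(ranked_a, ranked_b, step = NULL, clip = 320) {
  if (!setequal(ranked_a, ranked_b) || length(ranked_a) != length(ranked_b) ||
      anyDuplicated(ranked_a) || anyDuplicated(ranked_b))
    stop("ranked lists must be permutations of the same gene universe")
  N <- length(ranked_a)
  if (is.null(step)) step <- max(1L, N %/% 50L)
  thresholds <- unique(c(seq.int(step, N, by = step), N))
  # cumulative overlap counts via match positions
  pos_b <- match(ranked_a, ranked_b)
  map <- matrix(0, length(thresholds), length(thresholds),
                dimnames = list(thresholds, thresholds))
  for (ii in seq_along(thresholds)) {
    i <- thresholds[ii]
    in_top_b <- sort(pos_b[seq_len(i)])
    k_at <- findInterval(thresholds, in_top_b)  # overlap of top-i a with top-j b
    tail_p <- stats::phyper(k_at - 1, i, N - i, thresholds, lower.tail = FALSE)
    map[ii, ] <- pmin(clip, -log10(pmax(tail_p, 10^(-clip - 1))))
  }
  structure(list(map = map, thresholds = thresholds, step = step,
                 universe_size = N), class = "RRHOMap")
}
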