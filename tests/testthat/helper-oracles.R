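# Independent reference implementations used as oracles. These are written
# for clarity, not speed, and deliberately avoid the package's code paths.

# pairwise co-clustering frequencies by explicit pair enumeration
oracle_stability <- function(runs, n) {
  S <- matrix(NA_real_, n, n)
  co_cluster <- matrix(0L, n, n)
  co_present <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (run in runs) {
      pi <- match(i, run$present); pj <- match(j, run$present)
      if (!is.na(pi) && !is.na(pj)) {
        co_present[i, j] <- co_present[i, j] + 1L
        if (run$labels[pi] == run$labels[pj])
          co_cluster[i, j] <- co_cluster[i, j] + 1L
      }
    }
    for (j in seq_len(n))
      S[i, j] <- if (co_present[i, j] > 0) co_cluster[i, j] / co_present[i, j]
                 else 0.5
  }
  diag(S) <- 1
  list(S = S, co_cluster = co_cluster, co_present = co_present)
}

# naive O(n^3) average-linkage agglomeration on a distance matrix
oracle_average_linkage <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      dd <- mean(d[clusters[[a]], clusters[[b]]])
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (c_i in seq_along(clusters)) labels[clusters[[c_i]]] <- c_i
  labels
}

# Benjamini-Hochberg step-up, from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# two-sided exact Mann-Whitney p by full enumeration of rank splits
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  all_u <- apply(splits, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# hypergeometric upper tail P[X >= k] by enumeration over all draws
oracle_hyper_tail <- function(k, N, n_success, n_draw) {
  draws <- utils::combn(N, n_draw)
  mean(apply(draws, 2, function(d) sum(d <= n_success)) >= k)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small deterministic count matrix fixture
tiny_matrix <- function(n_genes = 12, n_cells = 8, seed = 1, mito = 2) {
  set.seed(seed)
  ids <- sprintf("G%03d", seq_len(n_genes))
  if (mito > 0) ids[seq_len(mito)] <- paste0("MT-", ids[seq_len(mito)])
  count_matrix(matrix(rpois(n_genes * n_cells, 3), n_genes),
               ids, sprintf("cell%03d", seq_len(n_cells)))
}
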