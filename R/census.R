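#' Define a perturbation plan for the clustering stability census
#'
#' The census re-clusters random subsets of the cells many times: for each
#' candidate number of clusters k, \code{n_subsets} subsets are drawn with
#' \code{drop_fraction} of the cells removed uniformly at random, and the
#' base clusterer is run \code{runs_per_subset} times per subset with
#' distinct derived seeds.
#'
#' @param k_range candidate cluster numbers (default 2:9).
#' @param n_subsets number of random subsets (default 10).
#' @param drop_fraction fraction of cells removed per subset (default 0.10).
#' @param runs_per_subset clustering repetitions per subset (default 10).
#' @param seed master seed; every subset and run seed is derived from it.
#' @return A \code{PerturbationPlan} object.
#' @export
perturbation_plan <- function(k_range = 2:9, n_subsets = 10,
                              drop_fraction = 0.10, runs_per_subset = 10,
                              seed = 1) {
  stopifnot(drop_fraction > 0, drop_fraction < 1, n_subsets >= 1,
            runs_per_subset >= 1, all(k_range >= 2))
  structure(list(k_range = as.integer(sort(unique(k_range))),
                 n_subsets = as.integer(n_subsets),
                 drop_fraction = drop_fraction,
                 runs_per_subset = as.integer(runs_per_subset),
                 seed = as.integer(seed)),
            class = "PerturbationPlan")
}

# stable arithmetic seed derivation: identical across platforms
derive_seed <- function(seed, subset, rep = 0L) {
  (as.double(seed) * 10007 + subset * 7919 + rep * 101) %% 2147483647
}

#' Default base clusterer: PCA + k-means on the log layer
#'
#' The census treats the base clusterer as pluggable (the original analysis
#' used SIMLR); the default takes log1p of the expression submatrix, the
#' top principal components, and k-means with the given seed.
#'
#' @param expr normalized genes x cells matrix (base matrix).
#' @param k number of clusters (>= 2, <= number of cells).
#' @param seed RNG seed for k-means initialization.
#' @param n_pcs number of principal components (default 30, capped by the
#'   data dimensions).
#' @param nstart k-means restarts (default 5).
#' @param pcs optional precomputed cells x PCs score matrix for
#'   \code{expr}; skips the log/PCA step when supplied.
#' @return Integer per-cell cluster labels in 1..k.
#' @export
base_cluster <- function(expr, k, seed = 1, n_pcs = 30, nstart = 5,
                         pcs = NULL) {
  n <- if (is.null(pcs)) ncol(expr) else nrow(pcs)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  if (is.null(pcs)) pcs <- pca_scores(expr, n_pcs)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  km <- NULL
  for (attempt in 0:2) {  # rare Hartigan-Wong empty-cluster failures: re-seed
    km <- tryCatch(stats::kmeans(pcs, centers = k, nstart = nstart,
                                 iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km)) break
    set.seed(seed + attempt + 1)
  }
  if (is.null(km)) stop("k-means failed to produce ", k, " clusters")
  if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
  as.integer(km$cluster)
}

# cells x PCs scores of log1p-transformed expression
pca_scores <- function(expr, n_pcs = 30) {
  x <- t(log1p(as.matrix(expr)))
  n_pcs <- min(n_pcs, nrow(x) - 1L, ncol(x))
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  p$x
}

#' Run the perturbed re-clusterings for one k
#'
#' Draws \code{n_subsets} subsets (each with \code{drop_fraction} of the
#' cells removed uniformly without replacement, from a subset-specific seed
#' derived from \code{plan$seed}) and clusters each subset
#' \code{runs_per_subset} times with distinct derived seeds. Fully
#' reproducible from \code{plan$seed}.
#'
#' @param expr normalized genes x cells matrix.
#' @param plan a \code{PerturbationPlan}.
#' @param k number of clusters passed to the base clusterer.
#' @param clusterer function \code{(expr, k, seed, ...)} returning per-cell
#'   labels; default \code{\link{base_cluster}}.
#' @param ... passed on to \code{clusterer}.
#' @return List of runs, each a list with \code{present} (sorted cell
#'   indices) and \code{labels} (cluster labels aligned with
#'   \code{present}).
#' @export
run_perturbations <- function(expr, plan, k, clusterer = base_cluster, ...) {
  stopifnot(inherits(plan, "PerturbationPlan"))
  n <- ncol(expr)
  n_drop <- round(plan$drop_fraction * n)
  runs <- vector("list", plan$n_subsets * plan$runs_per_subset)
  r <- 0L
  reuse_pca <- identical(clusterer, base_cluster)
  for (s in seq_len(plan$n_subsets)) {
    set.seed(derive_seed(plan$seed, s))
    present <- sort(sample.int(n, n - n_drop))
    sub <- expr[, present, drop = FALSE]
    pcs <- if (reuse_pca) pca_scores(sub) else NULL
    for (j in seq_len(plan$runs_per_subset)) {
      run_seed <- derive_seed(plan$seed, s, j)
      labels <- if (reuse_pca)
        clusterer(sub, k, seed = run_seed, pcs = pcs, ...)
      else clusterer(sub, k, seed = run_seed, ...)
      r <- r + 1L
      runs[[r]] <- list(present = present, labels = as.integer(labels))
    }
  }
  runs
}

#' Build the cell-by-cell clustering stability matrix
#'
#' For every pair of cells, counts the runs in which both were present
#' (\code{co_present}) and, of those, the runs in which they received the
#' same cluster label (\code{co_cluster}). The stability matrix S is their
#' ratio: the frequency with which two cells cluster together when both
#' survive the perturbation. The diagonal is 1. Pairs never co-present get
#' the uninformative prior 0.5 and are flagged.
#'
#' @param runs list of runs from \code{\link{run_perturbations}}.
#' @param n_cells total number of cells.
#' @return A \code{StabilityMatrix} list: \code{S}, \code{co_cluster},
#'   \code{co_present} (all n x n), and \code{never_co_present} (logical
#'   matrix flag).
#' @export
build_stability_matrix <- function(runs, n_cells) {
  co_cluster <- matrix(0L, n_cells, n_cells)
  co_present <- matrix(0L, n_cells, n_cells)
  for (run in runs) {
    present <- run$present
    if (length(run$labels) != length(present))
      stop("label vector does not match its present set")
    ones <- matrix(1L, length(present), length(present))
    co_present[present, present] <- co_present[present, present] + ones
    same <- outer(run$labels, run$labels, `==`)
    co_cluster[present, present] <- co_cluster[present, present] + same
  }
  never <- co_present == 0L
  S <- ifelse(never, 0.5, co_cluster / pmax(co_present, 1L))
  diag(S) <- 1
  diag(never) <- FALSE
  structure(list(S = S, co_cluster = co_cluster, co_present = co_present,
                 never_co_present = never),
            class = "StabilityMatrix")
}

#' Consensus partition of the stability matrix
#'
#' Transforms S into the Euclidean distance matrix between its rows and
#' cuts an average-linkage hierarchical clustering at k clusters.
#'
#' @param stab a \code{StabilityMatrix} (or a bare numeric S matrix).
#' @param k number of consensus clusters.
#' @return Integer per-cell labels in 1..k.
#' @export
consensus_partition <- function(stab, k) {
  S <- if (inherits(stab, "StabilityMatrix")) stab$S else as.matrix(stab)
  n <- nrow(S)
  if (k > n) stop("k (", k, ") exceeds the number of cells (", n, ")")
  hc <- stats::hclust(stats::dist(S, method = "euclidean"), method = "average")
  as.integer(stats::cutree(hc, k = k))
}

#' Per-cell, intra- and inter-cluster stability scores
#'
#' The per-cell stability is the mean of S between the cell and the other
#' members of its cluster (singletons score 1 by convention and are
#' flagged). The intra-cluster stability of a cluster is the mean S over
#' its unordered within-cluster pairs; the reported average is unweighted
#' over clusters. The inter-cluster stability is the mean S over all
#' between-cluster pairs.
#'
#' @param stab a \code{StabilityMatrix} (or bare S matrix).
#' @param labels per-cell cluster labels.
#' @return A list: \code{per_cell} (numeric vector),
#'   \code{intra_per_cluster} (named numeric), \code{intra} (their
#'   unweighted mean), \code{inter}, \code{singleton} (logical flags).
#' @export
stability_scores <- function(stab, labels) {
  S <- if (inherits(stab, "StabilityMatrix")) stab$S else as.matrix(stab)
  n <- nrow(S)
  stopifnot(length(labels) == n)
  labels <- as.integer(factor(labels))
  per_cell <- numeric(n)
  singleton <- logical(n)
  for (i in seq_len(n)) {
    mates <- setdiff(which(labels == labels[i]), i)
    if (length(mates)) per_cell[i] <- mean(S[i, mates])
    else { per_cell[i] <- 1; singleton[i] <- TRUE }
  }
  cl <- sort(unique(labels))
  intra_per_cluster <- vapply(cl, function(c) {
    members <- which(labels == c)
    if (length(members) < 2L) return(1)
    sm <- S[members, members]
    mean(sm[upper.tri(sm)])
  }, numeric(1))
  names(intra_per_cluster) <- cl
  between <- outer(labels, labels, `!=`) & upper.tri(S)
  inter <- if (any(between)) mean(S[between]) else NA_real_
  list(per_cell = per_cell, intra_per_cluster = intra_per_cluster,
       intra = mean(intra_per_cluster), inter = inter, singleton = singleton)
}

#' Automatic elbow selection of the number of clusters
#'
#' The original procedure chose k by visual inspection of the elbow of the
#' average intra-stability curve; this automates it as the interior k with
#' the sharpest elbow, measured by the (negative) discrete second
#' difference of the curve — the point where the curve bends hardest after
#' rising. Ties go to the smaller k; a flat or bend-free curve yields the
#' smallest interior k with a warning. The full curves are always reported
#' alongside so the choice can be overridden.
#'
#' @param intra named numeric vector of average intra-stability per k
#'   (names are the k values, at least 3).
#' @return The selected k (integer).
#' @export
select_k <- function(intra) {
  if (length(intra) < 3L)
    stop("need intra-stability for at least 3 values of k; choose k manually")
  ks <- as.integer(names(intra))
  stopifnot(!anyNA(ks))
  ord <- order(ks); ks <- ks[ord]; intra <- intra[ord]
  interior <- 2:(length(ks) - 1L)
  elbow <- -(intra[interior + 1L] - 2 * intra[interior] + intra[interior - 1L])
  if (max(elbow) <= 1e-12) {
    warning("no elbow in the intra-stability curve; ",
            "returning the smallest interior k")
    return(ks[interior[1L]])
  }
  ks[interior[which.max(elbow)]]
}

#' Flag unassigned cells by their stability score
#'
#' Cells whose per-cell stability is strictly below the threshold (default
#' 70\%) are labeled unassigned: their cluster membership varied too much
#' across the perturbed re-clusterings to be trusted.
#'
#' @param per_cell_stability numeric scores in [0, 1].
#' @param threshold strict lower bound (default 0.70).
#' @return Logical vector, \code{TRUE} for unassigned cells.
#' @export
label_unassigned <- function(per_cell_stability, threshold = 0.70) {
  stopifnot(all(per_cell_stability >= 0), all(per_cell_stability <= 1))
  per_cell_stability < threshold
}

#' Run the full clustering stability census
#'
#' For each k in the plan's range: perturbed re-clusterings, stability
#' matrix, consensus partition and stability scores; then automatic elbow
#' selection of k (overridable) and unassigned-cell flagging at the
#' selected k.
#'
#' @param expr normalized genes x cells matrix (or a \code{CountMatrix}).
#' @param plan a \code{PerturbationPlan}.
#' @param threshold unassigned-cell stability threshold (default 0.70).
#' @param k override the automatic choice of k (optional).
#' @param clusterer base clusterer, see \code{\link{run_perturbations}}.
#' @param keep_matrices keep each k's \code{StabilityMatrix} in the result
#'   (memory-heavy; default keeps only the selected k's).
#' @param ... passed to the clusterer.
#' @return A \code{ConsensusResult} list: \code{selected_k}, \code{labels}
#'   and \code{per_cell_stability} and \code{unassigned} at the selected k,
#'   \code{curves} (data frame of k, intra, inter), \code{per_k} (per-k
#'   labels and scores), \code{stability} (the selected k's
#'   \code{StabilityMatrix}).
#' @export
run_census <- function(expr, plan = perturbation_plan(), threshold = 0.70,
                       k = NULL, clusterer = base_cluster,
                       keep_matrices = FALSE, ...) {
  if (inherits(expr, "CountMatrix")) expr <- as.matrix(expr$values)
  n <- ncol(expr)
  per_k <- list()
  mats <- list()
  for (kk in plan$k_range) {
    runs <- run_perturbations(expr, plan, kk, clusterer = clusterer, ...)
    stab <- build_stability_matrix(runs, n)
    labels <- consensus_partition(stab, kk)
    sc <- stability_scores(stab, labels)
    per_k[[as.character(kk)]] <- list(labels = labels, scores = sc)
    mats[[as.character(kk)]] <- stab
  }
  intra <- vapply(per_k, function(x) x$scores$intra, numeric(1))
  inter <- vapply(per_k, function(x) x$scores$inter, numeric(1))
  selected_k <- if (!is.null(k)) as.integer(k) else select_k(intra)
  sel <- per_k[[as.character(selected_k)]]
  if (is.null(sel)) stop("k = ", selected_k, " was not evaluated by the plan")
  structure(list(
    selected_k = selected_k,
    labels = sel$labels,
    per_cell_stability = sel$scores$per_cell,
    unassigned = label_unassigned(sel$scores$per_cell, threshold),
    curves = data.frame(k = as.integer(names(per_k)), intra = unname(intra),
                        inter = unname(inter)),
    per_k = per_k,
    stability = if (keep_matrices) mats else mats[as.character(selected_k)],
    threshold = threshold, plan = plan), class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("Consensus census: selected k = %d; %d/%d cells unassigned (< %.0f%% stability)\n",
              x$selected_k, sum(x$unassigned), length(x$unassigned),
              100 * x$threshold))
  print(x$curves, row.names = FALSE)
  invisible(x)
}
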