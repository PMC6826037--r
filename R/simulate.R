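#' Define a branching differentiation lineage
#'
#' A lineage is a rooted tree of cell types, each occupying a fraction of
#' the population and a pseudotime interval on [0, 1] along its branch.
#' Cell types downstream of a branch point carry that branch's label;
#' shared (trunk) types belong to every branch.
#'
#' @param nodes character vector of cell-type names; the first is the root.
#' @param edges two-column character matrix (parent, child) forming a tree
#'   rooted at \code{nodes[1]}.
#' @param occupancy named numeric, expected fraction of cells per type;
#'   must sum to 1.
#' @param intervals named list of \code{c(lo, hi)} pseudotime intervals on
#'   [0, 1], one per type, ordered along each root-to-leaf path.
#' @return A \code{LineageSpec} object.
#' @export
lineage_spec <- function(nodes, edges, occupancy, intervals) {
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes), length(nodes) >= 1L)
  edges <- matrix(as.character(edges), ncol = 2L,
                  dimnames = list(NULL, c("parent", "child")))
  if (nrow(edges) != length(nodes) - 1L)
    stop("edges must form a tree: need exactly ", length(nodes) - 1L, " edges")
  if (!all(c(edges) %in% nodes)) stop("edge endpoints must be lineage nodes")
  if (nodes[1L] %in% edges[, "child"]) stop("root must have no parent")
  if (anyDuplicated(edges[, "child"])) stop("a node has two parents")
  miss <- setdiff(nodes[-1L], edges[, "child"])
  if (length(miss)) stop("disconnected nodes: ", paste(miss, collapse = ", "))
  occupancy <- occupancy[nodes]
  if (anyNA(occupancy)) stop("occupancy missing for some nodes")
  if (abs(sum(occupancy) - 1) > 1e-9) stop("occupancy fractions must sum to 1")
  intervals <- intervals[nodes]
  if (any(vapply(intervals, is.null, logical(1))))
    stop("pseudotime interval missing for some nodes")
  for (nm in nodes) {
    iv <- intervals[[nm]]
    if (length(iv) != 2L || iv[1L] > iv[2L] || iv[1L] < 0 || iv[2L] > 1)
      stop("invalid pseudotime interval for ", nm)
  }
  # child intervals must not start before their parent's
  for (e in seq_len(nrow(edges)))
    if (intervals[[edges[e, "child"]]][1L] < intervals[[edges[e, "parent"]]][1L])
      stop("pseudotime interval of ", edges[e, "child"],
           " starts before its parent's")
  obj <- structure(list(nodes = nodes, edges = edges, occupancy = occupancy,
                        intervals = intervals), class = "LineageSpec")
  obj$branch_points <- nodes[vapply(nodes, function(n)
    sum(edges[, "parent"] == n) > 1L, logical(1))]
  obj$branch_of <- lineage_branches(obj)
  obj
}

# label each node with its terminal branch ("trunk" for nodes shared by
# several leaves); branch names are the leaf names
lineage_branches <- function(lineage) {
  nodes <- lineage$nodes; edges <- lineage$edges
  children <- function(n) edges[edges[, "parent"] == n, "child"]
  leaves <- nodes[vapply(nodes, function(n) length(children(n)) == 0L, logical(1))]
  below <- function(n) {
    ch <- children(n)
    if (!length(ch)) return(n)
    unlist(lapply(ch, below))
  }
  vapply(nodes, function(n) {
    lv <- intersect(leaves, c(n, below(n)))
    if (length(lv) == 1L) lv else "trunk"
  }, character(1))
}

#' The default airway epithelium differentiation lineage
#'
#' Cycling basal cells feed basal, suprabasal and club cells, after which
#' the trajectory bifurcates into a secretory (goblet) branch and a
#' multiciliated branch, optionally via the transient deuterosomal
#' precursor stage.
#'
#' @param include_deuterosomal include the deuterosomal precursor between
#'   club and multiciliated cells (default \code{TRUE}).
#' @return A \code{LineageSpec}.
#' @export
airway_lineage <- function(include_deuterosomal = TRUE) {
  if (include_deuterosomal) {
    nodes <- c("cycling_basal", "basal", "suprabasal", "club",
               "goblet", "deuterosomal", "multiciliated")
    edges <- rbind(c("cycling_basal", "basal"), c("basal", "suprabasal"),
                   c("suprabasal", "club"), c("club", "goblet"),
                   c("club", "deuterosomal"), c("deuterosomal", "multiciliated"))
    occupancy <- c(cycling_basal = 0.10, basal = 0.20, suprabasal = 0.20,
                   club = 0.15, goblet = 0.10, deuterosomal = 0.10,
                   multiciliated = 0.15)
    intervals <- list(cycling_basal = c(0, 0.15), basal = c(0.15, 0.40),
                      suprabasal = c(0.40, 0.60), club = c(0.60, 0.78),
                      goblet = c(0.78, 1), deuterosomal = c(0.78, 0.90),
                      multiciliated = c(0.90, 1))
  } else {
    nodes <- c("cycling_basal", "basal", "suprabasal", "club",
               "goblet", "multiciliated")
    edges <- rbind(c("cycling_basal", "basal"), c("basal", "suprabasal"),
                   c("suprabasal", "club"), c("club", "goblet"),
                   c("club", "multiciliated"))
    occupancy <- c(cycling_basal = 0.12, basal = 0.20, suprabasal = 0.20,
                   club = 0.16, goblet = 0.14, multiciliated = 0.18)
    intervals <- list(cycling_basal = c(0, 0.15), basal = c(0.15, 0.40),
                      suprabasal = c(0.40, 0.60), club = c(0.60, 0.78),
                      goblet = c(0.78, 1), multiciliated = c(0.78, 1))
  }
  lineage_spec(nodes, edges, occupancy, intervals)
}

#' Define the gene expression program of a simulated dataset
#'
#' Draws per-gene lognormal baseline mean expression, plants one disjoint
#' marker module per cell type (elevated \code{marker_fold}-fold when the
#' type's pseudotime program is active), flags a fraction of genes as
#' mitochondrial (gene ids prefixed \code{"MT-"}) and fixes the
#' negative-binomial dispersion.
#'
#' @param lineage a \code{LineageSpec}; one marker module is planted per type.
#' @param n_genes total number of genes.
#' @param n_markers markers per cell type (default 15, the size of the
#'   marker lists used for cell-type scoring).
#' @param marker_fold multiplicative elevation of marker means in their own
#'   type (default 8).
#' @param marker_off off-state expression of marker genes as a fraction of
#'   their baseline mean (default 0): canonical cell-type markers (MUC5AC,
#'   FOXJ1, ...) are essentially silent outside their lineage stage, so the
#'   planted markers are fully off when their module is inactive; set a
#'   small positive value for leaky off-state expression. Applied only when
#'   \code{marker_fold > 1}; \code{marker_fold = 1} disables the marker
#'   program entirely (null simulation).
#' @param nb_dispersion negative-binomial dispersion (inverse size; default
#'   0.5). Scalar or per-gene.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial
#'   (default 0.02).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   per-gene baseline mean.
#' @param ramp_width logistic ramp width (pseudotime units) over which a
#'   marker module switches on/off at its interval boundaries.
#' @param seed RNG seed for the baseline draw.
#' @return An \code{ExpressionProgram} object.
#' @export
expression_program <- function(lineage, n_genes = 1000, n_markers = 15,
                               marker_fold = 8, marker_off = 0,
                               nb_dispersion = 0.5,
                               mito_gene_fraction = 0.02,
                               baseline_meanlog = log(0.2),
                               baseline_sdlog = 1, ramp_width = 0.02,
                               seed = 1) {
  stopifnot(inherits(lineage, "LineageSpec"), n_genes >= 1, n_markers >= 1,
            marker_fold > 0, all(nb_dispersion > 0),
            mito_gene_fraction >= 0, mito_gene_fraction < 1)
  types <- lineage$nodes
  n_mito <- round(mito_gene_fraction * n_genes)
  if (length(types) * n_markers + n_mito > n_genes)
    stop("marker sets (", length(types) * n_markers,
         " genes) do not fit within n_genes = ", n_genes)
  gene_ids <- sprintf("G%06d", seq_len(n_genes))
  if (n_mito > 0) {
    mito_idx <- seq.int(n_genes - n_mito + 1L, n_genes)
    gene_ids[mito_idx] <- paste0("MT-", gene_ids[mito_idx])
  }
  marker_sets <- stats::setNames(lapply(seq_along(types), function(i)
    seq.int((i - 1L) * n_markers + 1L, i * n_markers)), types)
  if (anyDuplicated(unlist(marker_sets))) stop("marker sets overlap")
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
  stopifnot(marker_off >= 0, marker_off <= 1)
  structure(list(n_genes = n_genes, gene_ids = gene_ids,
                 marker_sets = marker_sets, baseline_mean = baseline,
                 marker_fold = marker_fold, marker_off = marker_off,
                 nb_dispersion = rep_len(nb_dispersion, n_genes),
                 mito_gene_fraction = mito_gene_fraction,
                 ramp_width = ramp_width),
            class = "ExpressionProgram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logistic on/off activation of a module over its pseudotime interval
module_activation <- function(t, interval, width) {
  stats::plogis((t - interval[1L]) / width) *
    stats::plogis((interval[2L] - t) / width)
}

#' Simulate a branching-differentiation UMI count matrix with ground truth
#'
#' Draws cell types from the lineage occupancy, pseudotime uniformly within
#' each type's interval, lognormal library sizes, and UMI counts per
#' gene/cell from a negative binomial whose mean is the cell's library size
#' times the gene's relative expression. Marker modules ramp up over their
#' type's pseudotime interval with a logistic activation, so transitions
#' are smooth; dropout arises from the negative-binomial mass at zero.
#' Hybrid cells on the secretory-to-multiciliated transition carry BOTH the
#' goblet and multiciliated marker modules at >= 50\% activation, mirroring
#' double-positive (e.g. MUC5AC+/FOXJ1+) intermediates.
#'
#' @param lineage a \code{LineageSpec}.
#' @param program an \code{ExpressionProgram} built for \code{lineage}.
#' @param n_cells number of cells (>= 50).
#' @param hybrid_fraction fraction of all cells planted as hybrids, in
#'   [0, 0.5].
#' @param hybrid_mode \code{"binomial"} draws the hybrid count from
#'   Binomial(n_cells, hybrid_fraction); \code{"exact"} plants exactly
#'   \code{round(hybrid_fraction * n_cells)} hybrids.
#' @param hybrid_pair the two cell types whose marker modules hybrids
#'   co-express; both must be lineage nodes.
#' @param library_meanlog,library_sdlog lognormal parameters of the
#'   per-cell expected total UMI count.
#' @param high_mito_fraction fraction of cells planted with elevated
#'   mitochondrial content (QC fixture; default 0).
#' @param high_mito_factor fold elevation of mitochondrial expression in
#'   those cells (default 10).
#' @param seed RNG seed; identical seed and configuration give identical
#'   output.
#' @param return_means also return the dense matrix of negative-binomial
#'   means (for checking marginal statistics).
#' @return A list with elements \code{matrix} (raw \code{CountMatrix}),
#'   \code{truth} (per-cell data frame: barcode, cell_type, branch,
#'   pseudotime, is_hybrid, is_high_mito, library_size),
#'   \code{marker_sets} (named list of marker gene ids per type) and,
#'   optionally, \code{means}.
#' @export
generate_counts <- function(lineage, program, n_cells = 2000,
                            hybrid_fraction = 0,
                            hybrid_mode = c("binomial", "exact"),
                            hybrid_pair = c("goblet", "multiciliated"),
                            library_meanlog = log(3000), library_sdlog = 0.3,
                            high_mito_fraction = 0, high_mito_factor = 10,
                            seed = 1, return_means = FALSE) {
  stopifnot(inherits(lineage, "LineageSpec"),
            inherits(program, "ExpressionProgram"),
            n_cells >= 50, hybrid_fraction >= 0, hybrid_fraction <= 0.5)
  hybrid_mode <- match.arg(hybrid_mode)
  if (!setequal(intersect(names(program$marker_sets), lineage$nodes),
                lineage$nodes))
    stop("program marker sets do not cover the lineage nodes")
  if (anyDuplicated(unlist(program$marker_sets))) stop("marker sets overlap")
  if (hybrid_fraction > 0 && !all(hybrid_pair %in% lineage$nodes))
    stop("hybrid transition types (", paste(hybrid_pair, collapse = ", "),
         ") absent from lineage")

  set.seed(seed)
  types <- lineage$nodes
  cell_type <- sample(types, n_cells, replace = TRUE, prob = lineage$occupancy)
  iv <- do.call(rbind, lineage$intervals)[cell_type, , drop = FALSE]
  pseudotime <- stats::runif(n_cells, iv[, 1L], iv[, 2L])

  # trunk cells inherit a terminal branch, weighted by downstream occupancy
  branch_of <- lineage$branch_of
  leaves <- setdiff(unique(branch_of), "trunk")
  branch <- branch_of[cell_type]
  trunk <- which(branch == "trunk")
  if (length(trunk)) {
    w <- vapply(leaves, function(b)
      sum(lineage$occupancy[names(branch_of)[branch_of == b]]), numeric(1))
    branch[trunk] <- sample(leaves, length(trunk), replace = TRUE,
                            prob = w / sum(w))
  }
  library_size <- stats::rlnorm(n_cells, library_meanlog, library_sdlog)

  # per-type module activation for every cell; a module is visible only to
  # cells on a branch passing through its type
  act <- matrix(0, length(types), n_cells, dimnames = list(types, NULL))
  for (ty in types) {
    a <- module_activation(pseudotime, lineage$intervals[[ty]],
                           program$ramp_width)
    visible <- branch_of[[ty]] == "trunk" | branch == branch_of[[ty]]
    act[ty, ] <- a * visible
  }

  is_hybrid <- rep(FALSE, n_cells)
  if (hybrid_fraction > 0) {
    n_hyb <- if (hybrid_mode == "exact") round(hybrid_fraction * n_cells)
             else stats::rbinom(1L, n_cells, hybrid_fraction)
    eligible <- which(cell_type %in% hybrid_pair)
    if (n_hyb > length(eligible))
      stop("cannot plant ", n_hyb, " hybrids: only ", length(eligible),
           " cells have types in the hybrid transition")
    hyb <- sample(eligible, n_hyb)
    is_hybrid[hyb] <- TRUE
    # both modules at >= 50% activation, heterogeneous across cells
    act[hybrid_pair[1L], hyb] <- stats::runif(n_hyb, 0.5, 1)
    act[hybrid_pair[2L], hyb] <- stats::runif(n_hyb, 0.5, 1)
  }

  rel <- matrix(program$baseline_mean, program$n_genes, n_cells)
  if (program$marker_fold > 1) {
    off <- program$marker_off %||% 1
    for (ty in types) {
      gi <- program$marker_sets[[ty]]
      a <- rep(act[ty, ], each = length(gi))
      # off-state attenuation x on-state elevation; a=1 gives baseline*fold
      rel[gi, ] <- rel[gi, ] * (off + (1 - off) * a) *
        (1 + (program$marker_fold - 1) * a)
    }
  }

  is_high_mito <- rep(FALSE, n_cells)
  mito <- is_mito_gene(program$gene_ids)
  if (high_mito_fraction > 0 && any(mito)) {
    hm <- sample.int(n_cells, round(high_mito_fraction * n_cells))
    is_high_mito[hm] <- TRUE
    rel[mito, hm] <- rel[mito, hm] * high_mito_factor
  }

  mu <- sweep(rel, 2L, library_size / colSums(rel), `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = rep(1 / program$nb_dispersion, n_cells)),
                   nrow = program$n_genes)
  barcodes <- sprintf("cell_%06d", seq_len(n_cells))
  mat <- count_matrix(counts, program$gene_ids, barcodes, layer = "raw")
  truth <- data.frame(barcode = barcodes, cell_type = cell_type,
                      branch = branch, pseudotime = pseudotime,
                      is_hybrid = is_hybrid, is_high_mito = is_high_mito,
                      library_size = library_size)
  marker_ids <- lapply(program$marker_sets, function(i) program$gene_ids[i])
  out <- list(matrix = mat, truth = truth, marker_sets = marker_ids)
  if (return_means) out$means <- mu
  out
}

#' Write simulation ground truth as TSV
#'
#' @param sim result of \code{\link{generate_counts}}.
#' @param directory output directory.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(sim, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  markers <- data.frame(
    cell_type = rep(names(sim$marker_sets),
                    lengths(sim$marker_sets)),
    gene = unlist(sim$marker_sets, use.names = FALSE))
  write_tables(list(truth = sim$truth, marker_sets = markers), directory)
}
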