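#' Standard synthetic airway differentiation dataset
#'
#' The package's reference simulation for validating the full pipeline:
#' 600 cells over the six main airway epithelial cell types (cycling
#' basal, basal, suprabasal, club, goblet, multiciliated), 1,000 genes
#' with 15 planted markers per type at 8-fold elevation, negative-binomial
#' counts (dispersion 0.5) with lognormal library sizes.
#'
#' @param n_cells number of cells (default 600).
#' @param seed simulation seed.
#' @param hybrid_fraction fraction of planted goblet/multiciliated hybrid
#'   cells (default 0).
#' @param ... further arguments to \code{\link{generate_counts}}.
#' @return As \code{\link{generate_counts}}.
#' @export
sim_airway_standard <- function(n_cells = 600, seed = 1, hybrid_fraction = 0,
                                ...) {
  lin <- airway_lineage(include_deuterosomal = FALSE)
  prog <- expression_program(lin, n_genes = 1000, seed = 7)
  generate_counts(lin, prog, n_cells = n_cells,
                  hybrid_fraction = hybrid_fraction, seed = seed, ...)
}

#' Noisy transition-cell dataset for stability analysis
#'
#' Emulates a differentiation continuum whose populations are
#' distinguished by graded elevation (3-fold) of shared expression
#' programs rather than by exclusive on/off markers — the regime in which
#' cluster membership is genuinely uncertain — with 10\% planted hybrid
#' (transition) cells between the goblet and multiciliated programs.
#' Used to test that transition cells are enriched among low-stability
#' (unassigned) cells.
#'
#' @param n_cells number of cells (default 300).
#' @param seed simulation seed.
#' @param hybrid_fraction planted transition-cell fraction (default 0.10,
#'   exact count).
#' @return As \code{\link{generate_counts}}.
#' @export
sim_transition_noisy <- function(n_cells = 300, seed = 1,
                                 hybrid_fraction = 0.10) {
  lin <- airway_lineage(include_deuterosomal = FALSE)
  prog <- expression_program(lin, n_genes = 1000, marker_fold = 3,
                             marker_off = 1, seed = 7)
  generate_counts(lin, prog, n_cells = n_cells,
                  hybrid_fraction = hybrid_fraction, hybrid_mode = "exact",
                  seed = seed)
}

#' Secretory/multiciliated compartment with planted hybrid cells
#'
#' The double-positive quantification fixture: a population consisting
#' only of goblet and multiciliated cells (two sibling branches off a
#' zero-occupancy club root, so each cell expresses exactly one of the two
#' marker programs), with a planted exact-count fraction of hybrid cells
#' carrying both programs — the synthetic analogue of measuring
#' MUC5AC+/FOXJ1+ cells among goblet and multiciliated cells.
#'
#' @param n_cells number of cells (default 1000).
#' @param hybrid_fraction planted hybrid fraction of all cells (default
#'   0.089, exact count).
#' @param seed simulation seed.
#' @return As \code{\link{generate_counts}}; the flag genes for
#'   double-positive counting are the first goblet and first
#'   multiciliated marker (\code{marker_sets$goblet[1]},
#'   \code{marker_sets$multiciliated[1]}).
#' @export
sim_secretory_mcc_compartment <- function(n_cells = 1000,
                                          hybrid_fraction = 0.089,
                                          seed = 1) {
  lin <- lineage_spec(
    nodes = c("club", "goblet", "multiciliated"),
    edges = rbind(c("club", "goblet"), c("club", "multiciliated")),
    occupancy = c(club = 0, goblet = 0.5, multiciliated = 0.5),
    intervals = list(club = c(0, 0.05), goblet = c(0.05, 1),
                     multiciliated = c(0.05, 1)))
  prog <- expression_program(lin, n_genes = 500, seed = 7)
  generate_counts(lin, prog, n_cells = n_cells,
                  hybrid_fraction = hybrid_fraction, hybrid_mode = "exact",
                  seed = seed)
}
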