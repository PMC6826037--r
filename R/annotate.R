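#' Score cells against marker sets and assign cell types
#'
#' For each candidate cell type, the raw score of a cell is the mean
#' normalized expression of that type's marker genes in the cell,
#' producing a (types x cells) score matrix. Each type's row is then
#' z-scored across cells, and every cell is assigned the type with the
#' highest z-score (ties broken by raw score, then type-name order).
#' Marker genes absent from the matrix are dropped with a warning; at
#' least 5 usable markers per type are required.
#'
#' @param mat a normalized-layer \code{CountMatrix} (or bare matrix with
#'   gene-id rownames).
#' @param marker_sets named list: cell type -> character vector of marker
#'   gene ids.
#' @param z_across direction of z-scoring: \code{"cells"} (default;
#'   standardize each type's scores over cells) or \code{"types"}
#'   (standardize each cell's scores over types).
#' @param min_markers minimum usable markers per type (default 5).
#' @return A \code{CellTypeScores} list: \code{raw_scores} and
#'   \code{z_scores} (types x cells), \code{assignment} (per-cell type),
#'   \code{degenerate} (types whose raw scores had zero variance; their z
#'   is set to 0).
#' @export
score_cell_types <- function(mat, marker_sets, z_across = c("cells", "types"),
                             min_markers = 5) {
  z_across <- match.arg(z_across)
  v <- if (inherits(mat, "CountMatrix")) as.matrix(mat$values) else as.matrix(mat)
  stopifnot(is.list(marker_sets), !is.null(names(marker_sets)))
  types <- names(marker_sets)
  raw <- matrix(NA_real_, length(types), ncol(v),
                dimnames = list(types, colnames(v)))
  for (ty in types) {
    genes <- unique(as.character(marker_sets[[ty]]))
    present <- genes[genes %in% rownames(v)]
    if (length(present) < length(genes))
      warning(length(genes) - length(present), " marker gene(s) for '", ty,
              "' absent from the matrix; dropped")
    if (length(present) < min_markers)
      stop("cell type '", ty, "' has ", length(present),
           " usable marker genes (< ", min_markers, ")")
    raw[ty, ] <- colMeans(v[present, , drop = FALSE])
  }
  degenerate <- character(0)
  if (z_across == "cells") {
    z <- raw
    for (ty in types) {
      s <- stats::sd(raw[ty, ])
      if (is.na(s) || s == 0) {
        z[ty, ] <- 0
        degenerate <- c(degenerate, ty)
      } else z[ty, ] <- (raw[ty, ] - mean(raw[ty, ])) / s
    }
  } else {
    z <- apply(raw, 2L, function(col) {
      s <- stats::sd(col)
      if (is.na(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
    dimnames(z) <- dimnames(raw)
  }
  assignment <- vapply(seq_len(ncol(v)), function(i) {
    ord <- order(-z[, i], -raw[, i], types)
    types[ord[1L]]
  }, character(1))
  structure(list(raw_scores = raw, z_scores = z, assignment = assignment,
                 degenerate = degenerate), class = "CellTypeScores")
}

#' Aggregate per-cell type assignments to clusters
#'
#' Each cluster is assigned the modal per-cell type among its members,
#' with the agreement fraction; clusters with agreement below 0.5 are
#' labeled \code{"ambiguous"}.
#'
#' @param scores a \code{CellTypeScores} from \code{\link{score_cell_types}}.
#' @param labels per-cell cluster labels.
#' @return Data frame: \code{cluster}, \code{cell_type} (modal type or
#'   \code{"ambiguous"}), \code{modal_type}, \code{agreement},
#'   \code{n_cells}.
#' @export
assign_clusters <- function(scores, labels) {
  stopifnot(inherits(scores, "CellTypeScores"))
  labels <- as.character(labels)
  stopifnot(length(labels) == length(scores$assignment))
  clusters <- sort(unique(labels))
  rows <- lapply(clusters, function(cl) {
    members <- scores$assignment[labels == cl]
    tab <- sort(table(members), decreasing = TRUE)
    modal <- names(tab)[1L]
    agreement <- as.numeric(tab[1L]) / length(members)
    data.frame(cluster = cl,
               cell_type = if (agreement < 0.5) "ambiguous" else modal,
               modal_type = modal, agreement = agreement,
               n_cells = length(members))
  })
  do.call(rbind, rows)
}
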