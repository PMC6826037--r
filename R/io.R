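#' Construct a CountMatrix
#'
#' The central container of the pipeline: a genes x cells expression matrix
#' with gene identifiers, cell barcodes, per-gene mitochondrial flags and a
#' layer tag recording what the values are. The raw layer holds non-negative
#' integer UMI counts; normalized layers hold non-negative reals;
#' \code{"lognorm"} holds log1p of normalized values.
#'
#' @param values genes x cells matrix (base matrix or a \pkg{Matrix} sparse
#'   matrix). Raw-layer values must be non-negative integers.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param barcodes character vector of unique cell barcodes (columns).
#' @param is_mito optional logical per-gene flag; if \code{NULL} it is
#'   derived from \code{gene_ids} by the case-insensitive \code{"MT-"}
#'   prefix rule.
#' @param layer one of \code{"raw"}, \code{"normalized"}, \code{"lognorm"}.
#' @return An object of class \code{CountMatrix}.
#' @export
count_matrix <- function(values, gene_ids, barcodes, is_mito = NULL,
                         layer = c("raw", "normalized", "lognorm")) {
  layer <- match.arg(layer)
  if (is.null(dim(values)) || length(dim(values)) != 2L)
    stop("'values' must be a matrix")
  if (nrow(values) != length(gene_ids))
    stop("gene_ids length (", length(gene_ids), ") does not match row count (",
         nrow(values), ")")
  if (ncol(values) != length(barcodes))
    stop("barcodes length (", length(barcodes), ") does not match column count (",
         ncol(values), ")")
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene ids: ", paste(utils::head(
      unique(gene_ids[duplicated(gene_ids)]), 3L), collapse = ", "))
  if (anyDuplicated(barcodes))
    stop("duplicated cell barcodes: ", paste(utils::head(
      unique(barcodes[duplicated(barcodes)]), 3L), collapse = ", "))
  if (any(gene_ids == "")) stop("empty gene id")
  if (any(barcodes == "")) stop("empty cell barcode")
  if (min_value(values) < 0) stop("negative values in count matrix")
  if (layer == "raw" && !all_integerish(values))
    stop("raw layer must be integer-valued")
  if (is.null(is_mito)) is_mito <- is_mito_gene(gene_ids)
  stopifnot(length(is_mito) == length(gene_ids))
  rownames(values) <- gene_ids
  colnames(values) <- barcodes
  structure(list(values = values, gene_ids = gene_ids, barcodes = barcodes,
                 is_mito = as.logical(is_mito), layer = layer),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells [layer: %s; %d mito genes]\n",
              nrow(x$values), ncol(x$values), x$layer, sum(x$is_mito)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

is_mito_gene <- function(ids) grepl("^mt-", ids, ignore.case = TRUE)

min_value <- function(values) {
  if (length(values) == 0L) return(0)
  if (methods::is(values, "sparseMatrix")) {
    x <- values@x
    if (length(x) < length(values)) min(0, x) else min(x)
  } else min(values)
}

all_integerish <- function(values, tol = 1e-8) {
  x <- if (methods::is(values, "sparseMatrix")) values@x else as.numeric(values)
  length(x) == 0L || all(abs(x - round(x)) < tol)
}

# subset while keeping metadata in step
subset_matrix <- function(mat, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_along(mat$gene_ids) else genes
  ci <- if (is.null(cells)) seq_along(mat$barcodes) else cells
  count_matrix(mat$values[gi, ci, drop = FALSE], mat$gene_ids[gi],
               mat$barcodes[ci], mat$is_mito[gi], layer = mat$layer)
}

#' Write a CountMatrix as a 10x Genomics triplet directory
#'
#' Emits \code{matrix.mtx} (MatrixMarket integer coordinate, 1-based
#' indices), \code{features.tsv} (id, symbol) and \code{barcodes.tsv} into
#' \code{directory}, the plain-text layout produced by 10x Genomics
#' cell-counting pipelines. Round-trips bit-exactly through
#' \code{\link{read_10x_triplet}}.
#'
#' @param mat a raw-layer \code{CountMatrix}.
#' @param directory output directory; created if absent.
#' @return Invisibly, the paths of the three files written.
#' @export
write_10x_triplet <- function(mat, directory) {
  stopifnot(inherits(mat, "CountMatrix"))
  if (nrow(mat$values) == 0L || ncol(mat$values) == 0L)
    stop("refusing to write an empty matrix")
  if (mat$layer != "raw")
    stop("write_10x_triplet expects the raw integer layer")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(mat$values, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  tm <- Matrix::mat2triplet(m)
  mtx_path <- file.path(directory, "matrix.mtx")
  con <- file(mtx_path, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(tm$x))), con)
  if (length(tm$x))
    writeLines(sprintf("%d %d %d", tm$i, tm$j, as.integer(round(tm$x))), con)
  close(con)
  utils::write.table(data.frame(id = mat$gene_ids, symbol = mat$gene_ids),
                     file.path(directory, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(mat$barcodes, file.path(directory, "barcodes.tsv"))
  invisible(file.path(directory, c("matrix.mtx", "features.tsv", "barcodes.tsv")))
}

#' Read a 10x Genomics triplet directory
#'
#' Reads \code{matrix.mtx} plus features and barcodes files (either
#' \code{features.tsv}/\code{genes.tsv} naming is accepted). Orientation is
#' enforced to genes x cells: if the MatrixMarket dimensions match the
#' features/barcodes files only after transposition, the matrix is
#' transposed. Features files with 1 (id), 2 (id, symbol) or 3 (id, symbol,
#' type) columns are accepted; the symbol column, when present, drives
#' mitochondrial detection via the case-insensitive \code{"MT-"} prefix.
#'
#' @param directory path containing the three files.
#' @return A raw-layer \code{CountMatrix}.
#' @export
read_10x_triplet <- function(directory) {
  mtx_path <- file.path(directory, "matrix.mtx")
  if (!file.exists(mtx_path)) stop("matrix.mtx not found in ", directory)
  feat_path <- NULL
  for (cand in c("features.tsv", "genes.tsv", "features.txt"))
    if (file.exists(file.path(directory, cand))) {
      feat_path <- file.path(directory, cand); break
    }
  if (is.null(feat_path)) stop("no features file found in ", directory)
  bc_path <- file.path(directory, "barcodes.tsv")
  if (!file.exists(bc_path)) stop("barcodes.tsv not found in ", directory)

  m <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  feats <- utils::read.table(feat_path, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
  barcodes <- readLines(bc_path)
  n_genes <- nrow(feats); n_cells <- length(barcodes)
  if (nrow(m) == n_genes && ncol(m) == n_cells) {
    # already genes x cells
  } else if (nrow(m) == n_cells && ncol(m) == n_genes) {
    m <- Matrix::t(m)
  } else if (nrow(m) != n_genes) {
    stop(sprintf("matrix.mtx declares %d rows but %s has %d entries",
                 nrow(m), basename(feat_path), n_genes))
  } else {
    stop(sprintf("matrix.mtx declares %d columns but barcodes.tsv has %d entries",
                 ncol(m), n_cells))
  }
  ids <- feats[[1L]]
  symbols <- if (ncol(feats) >= 2L) feats[[2L]] else feats[[1L]]
  count_matrix(m, ids, barcodes, is_mito = is_mito_gene(symbols), layer = "raw")
}

#' Read a dense TSV count table
#'
#' Expects a header row of cell barcodes and a first column of gene ids;
#' remaining cells are numeric counts. Lossless for integer counts.
#'
#' @param path TSV file path.
#' @param layer layer tag for the result (default \code{"raw"}).
#' @return A \code{CountMatrix}.
#' @export
read_dense_tsv <- function(path, layer = "raw") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "")
  gene_ids <- tab[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicated gene id in ", path, ": ",
         unique(gene_ids[duplicated(gene_ids)])[1L])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at gene row %d, cell column %d of %s",
                 bad[1L], bad[2L], path))
  }
  count_matrix(num, gene_ids, colnames(vals), layer = layer)
}

#' Write a CountMatrix as a dense TSV count table
#'
#' @param mat a \code{CountMatrix}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_dense_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "CountMatrix"))
  df <- data.frame(gene = mat$gene_ids, as.matrix(mat$values),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write pipeline result tables as TSV files
#'
#' Writes each element of a named list of data frames to
#' \code{<directory>/<name>.tsv} with a header row.
#'
#' @param results named list of data frames.
#' @param directory output directory, created if absent.
#' @return Invisibly, the vector of paths written.
#' @export
write_tables <- function(results, directory) {
  stopifnot(is.list(results), !is.null(names(results)), all(names(results) != ""))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(directory, paste0(nm, ".tsv"))
    utils::write.table(as.data.frame(results[[nm]]), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
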