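test_that("QC metrics match their definitions", {
  m <- count_matrix(rbind(c(0, 0, 5),
                          c(0, 0, 0),
                          c(2, 3, 5)),
                    c("MT-g1", "g2", "g3"), c("c1", "c2", "c3"))
  qc <- compute_qc(m)
  # cell c1: counts (0, 0, 2) over 3 genes
  expect_identical(qc$n_features, c(1L, 1L, 2L))
  expect_equal(qc$dropout_pct, c(2 / 3, 2 / 3, 1 / 3))
  expect_equal(qc$library_size, c(2, 3, 10))
  # cell c3 has 5 of 10 UMI on the MT- gene
  expect_equal(qc$mito_pct, c(0, 0, 0.5))
  expect_true(all(qc$library_size >= qc$n_features))
})

test_that("an all-zero cell has zero features and full dropout", {
  m <- count_matrix(cbind(c(0, 0), c(1, 2)), c("g1", "g2"), c("c1", "c2"))
  qc <- compute_qc(m)
  expect_identical(qc$n_features[1], 0L)
  expect_equal(qc$dropout_pct[1], 1)
  expect_error(compute_qc(count_matrix(matrix(integer(0), 0, 0),
                                       character(0), character(0))), "empty")
})

test_that("identical metrics remove nobody (strict percentile rule)", {
  vals <- matrix(rep(c(1, 0, 2), 25), 3)
  m <- count_matrix(vals, c("g1", "g2", "g3"), sprintf("c%02d", 1:25))
  res <- filter_cells(m, compute_qc(m))
  expect_length(res$report$kept_cells, 25)
  expect_identical(nrow(res$report$removed_cells), 0L)
})

test_that("an extreme library-size outlier is removed with reason libsize_high", {
  set.seed(7)
  vals <- matrix(rpois(30 * 40, 2), 30)
  vals[, 40] <- vals[, 40] * 100
  m <- count_matrix(vals, sprintf("g%02d", 1:30), sprintf("c%02d", 1:40))
  res <- filter_cells(m, compute_qc(m))
  expect_true("c40" %in% res$report$removed_cells$barcode)
  reasons <- res$report$removed_cells$reasons[
    res$report$removed_cells$barcode == "c40"]
  expect_match(reasons, "libsize_high")
})

test_that("filtering conserves cells and matches a sort-based quantile oracle", {
  set.seed(13)
  vals <- matrix(rnbinom(200 * 100, mu = 2, size = 1), 200)
  m <- count_matrix(vals, sprintf("g%03d", 1:200), sprintf("c%03d", 1:100))
  qc <- compute_qc(m)
  res <- filter_cells(m, qc)
  expect_identical(length(res$report$kept_cells) +
                   nrow(res$report$removed_cells), 100L)
  # independent check of one bound: strictly above the sorted 95th percentile
  q95 <- stats::quantile(qc$library_size, 0.95, type = 7, names = FALSE)
  expect_setequal(
    qc$barcode[qc$library_size > q95],
    res$report$removed_cells$barcode[
      grepl("libsize_high", res$report$removed_cells$reasons)])
  # at most 4 x 5% + 5% of cells removed (plus interpolation slack)
  expect_lte(nrow(res$report$removed_cells), ceiling(0.25 * 100) + 5)
})

test_that("planted high-mito cells are all removed", {
  lin <- airway_lineage(FALSE)
  prog <- expression_program(lin, n_genes = 500, seed = 3)
  sim <- generate_counts(lin, prog, n_cells = 200, high_mito_fraction = 0.03,
                         seed = 6)
  res <- filter_cells(sim$matrix, compute_qc(sim$matrix))
  planted <- sim$truth$barcode[sim$truth$is_high_mito]
  expect_true(all(planted %in% res$report$removed_cells$barcode))
})

test_that("gene filter keeps >= 5 detected cells, removes 4, and is idempotent", {
  vals <- matrix(0L, 3, 10)
  vals[1, 1:5] <- 1L   # detected in exactly 5 cells -> kept
  vals[2, 1:4] <- 7L   # detected in 4 cells -> removed
  m <- count_matrix(vals, c("keep5", "drop4", "zero"), sprintf("c%02d", 1:10))
  f <- filter_genes(m)
  expect_identical(f$gene_ids, "keep5")
  expect_identical(filter_genes(f)$gene_ids, f$gene_ids)
})

test_that("unsupervised normalization scales by median library size", {
  # two cells with libraries 100 and 300: median 200, factors 0.5 and 1.5
  vals <- cbind(c(60L, 40L), c(180L, 120L))
  m <- count_matrix(vals, c("g1", "g2"), c("c1", "c2"))
  norm <- normalize_counts(m)
  expect_equal(attr(norm, "scale_factors"), c(0.5, 1.5))
  expect_equal(as.matrix(norm$values), cbind(c(120, 80), c(120, 80)),
               ignore_attr = TRUE)
  # identical cells: factors 1, matrix unchanged
  m2 <- count_matrix(cbind(c(2L, 3L), c(2L, 3L)), c("g1", "g2"),
                     c("c1", "c2"))
  norm2 <- normalize_counts(m2)
  expect_equal(as.matrix(norm2$values), as.matrix(m2$values) * 1,
               ignore_attr = TRUE)
})

test_that("cluster-guided pass equalizes a planted library-size doubling", {
  set.seed(31)
  base_mean <- rgamma(150, 2, 1)
  a <- matrix(rpois(150 * 250, base_mean), 150)
  b <- matrix(rpois(150 * 250, 2 * base_mean), 150)  # 2x deeper type
  m <- count_matrix(cbind(a, b), sprintf("g%03d", 1:150),
                    sprintf("c%03d", 1:500))
  labels <- rep(c("A", "B"), each = 250)
  norm <- normalize_counts(m, labels = labels)
  v <- as.matrix(norm$values)
  mean_a <- rowMeans(v[, 1:250]); mean_b <- rowMeans(v[, 251:500])
  keep <- base_mean > 2
  expect_lt(stats::median(abs(mean_a - mean_b)[keep] /
                          ((mean_a + mean_b) / 2)[keep]), 0.05)
})

test_that("small clusters fall back to pass-1 factors", {
  m <- tiny_matrix(10, 8, mito = 0)
  labels <- c(rep("big", 6), "tiny", "tiny")
  expect_message(normalize_counts(m, labels = labels), "fewer than 3 cells")
})

test_that("normalization conserves within-cell gene rank order", {
  sim <- sim_airway_standard(n_cells = 80, seed = 3)
  norm <- normalize_counts(sim$matrix)
  raw <- as.matrix(sim$matrix$values)
  v <- as.matrix(norm$values)
  for (i in c(1, 40, 80))
    expect_identical(order(raw[, i]), order(v[, i]))
})

test_that("highly variable gene selection finds planted markers", {
  sim <- sim_airway_standard(n_cells = 400, seed = 8)
  norm <- normalize_counts(filter_genes(sim$matrix))
  hvg <- select_hvg(norm, 300)
  planted <- unlist(sim$marker_sets)
  expect_gte(mean(planted %in% names(hvg)), 0.9)
  # all genes returned when n_top equals the gene count
  all_sel <- select_hvg(norm, nrow(norm$values))
  expect_setequal(names(all_sel), norm$gene_ids)
  expect_error(select_hvg(norm, nrow(norm$values) + 1), "n_top")
})

test_that("a constant-expression gene is never selected over variable ones", {
  set.seed(4)
  vals <- rbind(matrix(rpois(50 * 60, 5), 50), rep(3, 60))
  m <- count_matrix(vals, c(sprintf("g%02d", 1:50), "constant"),
                    sprintf("c%02d", 1:60), layer = "normalized")
  expect_false("constant" %in% names(select_hvg(m, 25)))
})
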