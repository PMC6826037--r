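test_that("positivity rules: detected counts nonzero, percentile uses the
           median of positive cells", {
  v <- matrix(c(0, 0, 1, 2, 3, 4), 1,
              dimnames = list("g", sprintf("c%d", 1:6)))
  det <- positive_cells(v, "g", "detected")
  expect_identical(sum(det), 4L)
  pct <- positive_cells(v, "g", "percentile")
  # median of positives {1,2,3,4} = 2.5 -> cells with 3 and 4
  expect_identical(unname(which(pct)), 5:6)
  expect_equal(attr(pct, "threshold"), 2.5)
  zero <- matrix(0, 1, 4, dimnames = list("g", sprintf("c%d", 1:4)))
  expect_false(any(positive_cells(zero, "g", "detected")))
  expect_false(any(positive_cells(zero, "g", "percentile")))
  expect_error(positive_cells(v, "nope"), "absent")
})

test_that("double-positive fraction counts and intervals are exact", {
  # 10 cells: 3 A-only, 5 B-only, 2 both
  v <- rbind(A = c(1, 1, 1, 0, 0, 0, 0, 0, 2, 2),
             B = c(0, 0, 0, 1, 1, 1, 1, 1, 2, 2))
  colnames(v) <- sprintf("c%02d", 1:10)
  dp <- double_positive_fraction(v, "A", "B")
  expect_equal(dp$fraction, 0.2)
  expect_identical(dp$n_double, 2L)
  expect_identical(dp$n_denominator, 10L)
  expect_equal(dp$ci, as.numeric(stats::binom.test(2, 10)$conf.int))
  # symmetric in the two genes
  dp2 <- double_positive_fraction(v, "B", "A")
  expect_equal(dp2$fraction, dp$fraction)
  # denominator "all" and explicit subsets
  v0 <- rbind(A = c(1, 0, 0, 0), B = c(0, 1, 0, 0))
  colnames(v0) <- sprintf("c%d", 1:4)
  expect_equal(double_positive_fraction(v0, "A", "B", denominator = "all")$fraction, 0)
  expect_equal(double_positive_fraction(v0, "A", "B",
                                        denominator = c(1, 2))$n_denominator, 2L)
  # empty denominator is undefined
  none <- rbind(A = c(0, 0), B = c(0, 0)); colnames(none) <- c("c1", "c2")
  expect_message(res <- double_positive_fraction(none, "A", "B"), "undefined")
  expect_true(is.na(res$fraction))
})

test_that("planted hybrid fraction is recovered within its exact CI", {
  sim <- sim_secretory_mcc_compartment(n_cells = 1000,
                                       hybrid_fraction = 0.089, seed = 3)
  expect_identical(sum(sim$truth$is_hybrid), 89L)
  norm <- normalize_counts(sim$matrix)
  dp <- double_positive_fraction(norm, sim$marker_sets$goblet[1],
                                 sim$marker_sets$multiciliated[1],
                                 rule = "detected", denominator = "either")
  expect_true(dp$ci[1] <= 0.089 && 0.089 <= dp$ci[2])
})

test_that("cell ordering is branch, then cluster emergence, then pseudotime", {
  pt <- c(0.9, 0.1, 0.5, 0.8, 0.2, 0.6)
  br <- c("b", "a", "a", "b", "a", "b")
  cl <- c(2, 1, 1, 2, 1, 2)
  ord <- order_cells(pt, br, cl)
  expect_identical(br[ord], c("a", "a", "a", "b", "b", "b"))
  expect_true(all(diff(pt[ord][1:3]) > 0))
  # clusters ordered by median pseudotime within a branch
  pt2 <- c(0.65, 0.7, 0.75, 0.1, 0.2, 0.9)
  cl2 <- c("late", "late", "late", "early", "early", "early")
  ord2 <- order_cells(pt2, rep("x", 6), cl2)
  expect_identical(cl2[ord2], rep(c("early", "late"), each = 3))
  # single branch, single cluster: pure pseudotime order
  expect_identical(order_cells(pt, rep("x", 6), rep(1, 6)), order(pt))
  expect_error(order_cells(c(0.1, NA), c("a", "a"), c(1, 1)),
               "missing pseudotime")
})

test_that("ordering is invariant to a permutation of the input cells", {
  sim <- sim_airway_standard(n_cells = 120, seed = 17)
  tr <- sim$truth
  ord <- order_cells(tr$pseudotime, tr$branch, tr$cell_type, tr$barcode)
  set.seed(1); perm <- sample(nrow(tr))
  ord_p <- order_cells(tr$pseudotime[perm], tr$branch[perm],
                       tr$cell_type[perm], tr$barcode[perm])
  expect_identical(tr$barcode[ord], tr$barcode[perm][ord_p])
  # within each branch pseudotime is non-decreasing within each cluster run
  for (b in unique(tr$branch)) {
    sub <- ord[tr$branch[ord] == b]
    for (ty in unique(tr$cell_type[sub]))
      expect_true(!is.unsorted(tr$pseudotime[sub[tr$cell_type[sub] == ty]]))
  }
})

test_that("smoothing reproduces the hand-computed windowed z profile", {
  v <- matrix(c(0, 0, 0, 10, 10, 10), 1,
              dimnames = list("g", sprintf("c%d", 1:6)))
  sm <- smooth_expression(v, ordering = 1:6, window = 3)
  expect_equal(unname(sm$smoothed[1, ]),
               c(-1, -1, -1 / 3, 1 / 3, 1, 1))
  # window 1 is the identity on z-scores
  sm1 <- smooth_expression(v, 1:6, window = 1)
  expect_equal(unname(sm1$smoothed[1, ]), c(-1, -1, -1, 1, 1, 1))
  # constant gene: all zeros, flagged
  vc <- rbind(v, flat = 5)
  smc <- smooth_expression(vc, 1:6, window = 3)
  expect_equal(unname(smc$smoothed["flat", ]), rep(0, 6))
  expect_identical(smc$zero_variance, "flat")
  expect_error(smooth_expression(v, 1:6, window = 7), "window")
})

test_that("smoothing respects branch boundaries and preserves the z mean", {
  v <- matrix(c(0, 0, 0, 9, 9, 9), 1,
              dimnames = list("g", sprintf("c%d", 1:6)))
  branch <- rep(c("a", "b"), each = 3)
  sm <- smooth_expression(v, 1:6, window = 3, branch = branch)
  # z is constant within each branch segment: smoothing leaves it unchanged
  expect_equal(unname(sm$smoothed[1, ]), c(-1, -1, -1, 1, 1, 1))
  set.seed(9)
  vr <- matrix(rnorm(300), 3, 100,
               dimnames = list(c("x", "y", "z"), NULL))
  smr <- smooth_expression(vr, sample(100), window = 10)
  for (g in 1:3)
    expect_lt(abs(mean(smr$smoothed[g, ])), 10 / 100)
})

test_that("smoothed planted markers peak inside their activation interval", {
  sim <- sim_airway_standard(n_cells = 400, seed = 37)
  tr <- sim$truth
  norm <- normalize_counts(filter_genes(sim$matrix))
  ord <- order_cells(tr$pseudotime, tr$branch, tr$cell_type, tr$barcode)
  sm <- smooth_expression(norm, ord, window = 10, branch = tr$branch)
  lin <- airway_lineage(FALSE)
  hits <- 0; total <- 0
  for (ty in names(sim$marker_sets)) {
    iv <- lin$intervals[[ty]]
    for (g in sim$marker_sets[[ty]]) {
      if (!g %in% rownames(sm$smoothed)) next
      total <- total + 1
      peak_cell <- ord[which.max(sm$smoothed[g, ])]
      pt <- tr$pseudotime[peak_cell]
      if (pt >= iv[1] - 0.05 && pt <= iv[2] + 0.05) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})
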