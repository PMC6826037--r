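make_runs <- function(n, n_runs, seed, k = 3) {
  # random fixtures: random subsets of cells with random labels
  set.seed(seed)
  lapply(seq_len(n_runs), function(r) {
    present <- sort(sample.int(n, max(2, rbinom(1, n, 0.8))))
    list(present = present,
         labels = sample.int(k, length(present), replace = TRUE))
  })
}

test_that("stability matrix equals exhaustive pair counting on small fixtures", {
  for (case in 1:8) {
    n <- sample(4:12, 1)
    runs <- make_runs(n, n_runs = sample(1:5, 1), seed = case)
    got <- build_stability_matrix(runs, n)
    ref <- oracle_stability(runs, n)
    expect_identical(got$co_cluster, ref$co_cluster)
    expect_identical(got$co_present, ref$co_present)
    expect_equal(got$S, ref$S)
  }
})

test_that("the worked 6-cell example gives the hand-computed frequencies", {
  runs <- list(
    list(present = 1:5, labels = c(1L, 1L, 2L, 2L, 1L)),
    list(present = 1:6, labels = c(1L, 1L, 2L, 2L, 2L, 1L)),
    list(present = 1:6, labels = c(1L, 1L, 1L, 2L, 2L, 1L)))
  stab <- build_stability_matrix(runs, 6)
  expect_equal(stab$S[1, 2], 1)       # together in all 3 runs
  expect_equal(stab$S[3, 4], 2 / 3)
  expect_equal(stab$S[1, 6], 1)       # cell 6 absent in run 1: 2 of 2
  # per-cell stability under clusters {1,2,6}, {3,4,5}
  sc <- stability_scores(stab, c(1, 1, 2, 2, 2, 1))
  expect_equal(sc$per_cell[1], mean(c(stab$S[1, 2], stab$S[1, 6])))
  expect_equal(sc$per_cell[1], 1)
})

test_that("stability matrices are symmetric, bounded, unit-diagonal", {
  for (seed in 1:4) {
    n <- 15
    runs <- make_runs(n, 6, seed = seed + 100)
    stab <- build_stability_matrix(runs, n)
    expect_identical(stab$S, t(stab$S))
    expect_true(all(stab$S >= 0 & stab$S <= 1))
    expect_true(all(diag(stab$S) == 1))
    expect_true(all(stab$co_cluster <= stab$co_present))
  }
})

test_that("never co-present pairs get the 0.5 prior and are flagged", {
  runs <- list(list(present = c(1L, 2L), labels = c(1L, 1L)),
               list(present = c(3L, 4L), labels = c(1L, 2L)))
  stab <- build_stability_matrix(runs, 4)
  expect_equal(stab$S[1, 3], 0.5)
  expect_true(stab$never_co_present[1, 3])
  expect_false(stab$never_co_present[1, 2])
  # mismatched labels are rejected
  expect_error(build_stability_matrix(
    list(list(present = 1:3, labels = 1:2)), 3), "present set")
})

test_that("consensus partition recovers blocks and matches a naive
           average-linkage oracle", {
  S <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 2)),
             cbind(matrix(0, 2, 3), matrix(1, 2, 2)))
  labels <- consensus_partition(S, 2)
  expect_identical(length(unique(labels[1:3])), 1L)
  expect_identical(length(unique(labels[4:5])), 1L)
  expect_false(labels[1] == labels[4])
  expect_identical(sort(unique(consensus_partition(S, 5))), 1:5)
  expect_error(consensus_partition(S, 6), "exceeds")

  for (seed in 1:5) {
    set.seed(seed)
    R <- matrix(runif(100), 10); R <- (R + t(R)) / 2; diag(R) <- 1
    d <- stats::dist(R)
    for (k in c(2, 4)) {
      got <- consensus_partition(R, k)
      ref <- oracle_average_linkage(d, k)
      expect_gt(adjusted_rand(got, ref), 0.999)
    }
  }
})

test_that("stability scores: perfect blocks, singletons, permuted labels", {
  S <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), matrix(1, 3, 3)))
  sc <- stability_scores(S, rep(1:2, each = 3))
  expect_equal(sc$per_cell, rep(1, 6))
  expect_equal(sc$intra, 1)
  expect_equal(sc$inter, 0)
  # singleton convention
  sc2 <- stability_scores(S, c(1, 1, 1, 2, 2, 3))
  expect_equal(sc2$per_cell[6], 1)
  expect_true(sc2$singleton[6])
  # random labels on block S: intra ~ inter
  set.seed(2)
  rl <- sample(rep(1:2, each = 3))
  sc3 <- stability_scores(S, rl)
  expect_lt(abs(sc3$intra - sc3$inter), 0.6)
})

test_that("perturbation runs have the right size and are reproducible", {
  set.seed(1)
  expr <- matrix(rpois(50 * 100, 3), 50)
  plan <- perturbation_plan(k_range = 2:4, n_subsets = 3,
                            runs_per_subset = 2, seed = 77)
  runs <- run_perturbations(expr, plan, k = 3)
  expect_length(runs, 6)
  for (run in runs) {
    expect_length(run$present, 90)  # 10% of 100 cells removed
    expect_length(run$labels, 90)
  }
  runs2 <- run_perturbations(expr, plan, k = 3)
  expect_identical(runs, runs2)
  plan1 <- perturbation_plan(n_subsets = 1, runs_per_subset = 1, seed = 5)
  expect_length(run_perturbations(expr, plan1, k = 2), 1)
})

test_that("base clusterer separates Gaussian blobs and validates k", {
  set.seed(3)
  blob <- cbind(matrix(rpois(30 * 20, 1), 30),
                matrix(rpois(30 * 20, 1), 30) + 40L)
  labels <- base_cluster(blob, 2, seed = 1)
  expect_equal(adjusted_rand(labels, rep(1:2, each = 20)), 1)
  expect_error(base_cluster(blob, 1, seed = 1), "at least 2")
  expect_error(base_cluster(blob, 41, seed = 1), "exceeds")
})

test_that("elbow selection finds the sharpest bend; degenerate curves warn", {
  curve <- c(`2` = 0.60, `3` = 0.75, `4` = 0.97, `5` = 0.98, `6` = 0.98)
  expect_identical(select_k(curve), 4L)
  expect_warning(k_flat <- select_k(c(`2` = 0.9, `3` = 0.9, `4` = 0.9)),
                 "no elbow")
  expect_identical(k_flat, 3L)
  expect_warning(k_lin <- select_k(c(`2` = 0.1, `3` = 0.2, `4` = 0.3,
                                     `5` = 0.4)), "no elbow")
  expect_identical(k_lin, 3L)
  expect_error(select_k(c(`2` = 0.5, `3` = 0.6)), "at least 3")
})

test_that("unassigned labeling is strictly below threshold", {
  flags <- label_unassigned(c(0.70, 0.69, 1, 0, 0.7000001))
  expect_identical(flags, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_error(label_unassigned(c(0.5, 1.2)), "per_cell_stability")
})

test_that("census on planted 6-type data recovers the types", {
  sim <- sim_airway_standard(n_cells = 240, seed = 19)
  norm <- normalize_counts(filter_genes(sim$matrix))
  expr <- as.matrix(norm$values[select_hvg(norm, 200), ])
  plan <- perturbation_plan(k_range = 4:7, n_subsets = 4,
                            runs_per_subset = 3, seed = 9)
  res <- run_census(expr, plan)
  expect_identical(res$selected_k, 6L)
  expect_gte(adjusted_rand(res$labels, sim$truth$cell_type), 0.9)
  expect_gte(mean(res$per_cell_stability), 0.95)
  # bit-exact reproducibility from the plan seed
  res2 <- run_census(expr, plan)
  expect_identical(res$labels, res2$labels)
  expect_identical(res$per_cell_stability, res2$per_cell_stability)
  expect_identical(res$curves, res2$curves)
})

test_that("weakening the planted signal never increases mean stability", {
  lin <- airway_lineage(FALSE)
  stab_at <- function(fold) {
    prog <- expression_program(lin, n_genes = 400, nb_dispersion = 0.5,
                               marker_fold = fold, marker_off = 1, seed = 7)
    sim <- generate_counts(lin, prog, n_cells = 150, seed = 23)
    norm <- normalize_counts(filter_genes(sim$matrix))
    expr <- as.matrix(norm$values[select_hvg(norm, 150), ])
    plan <- perturbation_plan(k_range = 6, n_subsets = 5,
                              runs_per_subset = 2, seed = 3)
    runs <- run_perturbations(expr, plan, 6)
    stab <- build_stability_matrix(runs, ncol(expr))
    mean(stability_scores(stab, consensus_partition(stab, 6))$per_cell)
  }
  s <- vapply(c(6, 2.5, 1.3), stab_at, numeric(1))
  expect_true(s[1] >= s[2] - 0.02 && s[2] >= s[3] - 0.02)
})
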