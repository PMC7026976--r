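sim5 <- function(n_genes = 60, seed = 42) {
  sizes <- c(t1 = 6, t2 = 10, t3 = 4, t4 = 8, t5 = 12)
  simulate_counts(n_genes, sizes, seed = seed)
}

test_that("multiply-mode induction scales targets only; factor 1 is the identity", {
  sim <- sim5()
  genes <- rownames(sim$counts)[1:5]
  same <- induce_specificity(sim$counts, sim$grouping, genes, "t2",
                             mode = "multiply", factor = 1)
  expect_identical(same, sim$counts)
  up <- induce_specificity(sim$counts, sim$grouping, genes, "t2",
                           mode = "multiply", factor = 5)
  in_t2 <- sim$grouping$assignment[colnames(sim$counts)] == "t2"
  expect_identical(up[genes, in_t2], sim$counts[genes, in_t2] * 5)
  expect_identical(up[genes, !in_t2], sim$counts[genes, !in_t2])
  other <- setdiff(rownames(sim$counts), genes)
  expect_identical(up[other, ], sim$counts[other, ])
  # zeros stay zero under multiplication
  expect_identical(which(up[genes, in_t2] == 0),
                   which(sim$counts[genes, in_t2] == 0))
  expect_error(induce_specificity(sim$counts, sim$grouping, "ghost", "t2",
                                  mode = "multiply", factor = 2), "unknown genes")
  expect_error(induce_specificity(sim$counts, sim$grouping, genes, "nope",
                                  mode = "multiply", factor = 2), "unknown target")
})

test_that("add-mode induction shifts by the constant and preserves variance at factor 1", {
  sim <- sim5()
  genes <- rownames(sim$counts)[1:4]
  shifted <- induce_specificity(sim$counts, sim$grouping, genes, "t4",
                                mode = "add", factor = 100)
  in_t4 <- sim$grouping$assignment[colnames(sim$counts)] == "t4"
  expect_identical(shifted[genes, in_t4], sim$counts[genes, in_t4] + 100)
  for (g in genes)
    expect_equal(var(shifted[g, in_t4]), var(sim$counts[g, in_t4]),
                 tolerance = 1e-12)
})

test_that("variance inflation multiplies the spread while keeping the mean", {
  grp <- sample_grouping(paste0("s", 1:40), rep(c("T", "O"), each = 20))
  # continuous matrix so the mean/variance identity is exact (no rounding)
  set.seed(9)
  m <- matrix(runif(40, 0, 5) + 0.1, 1, 40,
              dimnames = list("g", paste0("s", 1:40)))
  out <- induce_specificity(m, grp, "g", "T", mode = "add", factor = 100,
                            variance_factor = 9)
  tcols <- paste0("s", 1:20)
  base <- m["g", tcols] + 100
  expect_equal(mean(out["g", tcols]), mean(base), tolerance = 1e-10)
  expect_equal(var(out["g", tcols]), 9 * var(base), tolerance = 1e-10)
  # integral input stays integral (rounded after inflation)
  mi <- matrix(rpois(40, 5), 1, 40, dimnames = dimnames(m))
  outi <- induce_specificity(mi, grp, "g", "T", mode = "add", factor = 100,
                             variance_factor = 25)
  expect_true(all(outi == round(outi)) && all(outi >= 0))
  expect_error(induce_specificity(m, grp, "g", "T", mode = "multiply",
                                  factor = 2, variance_factor = 2),
               "'add' mode")
})

test_that("rank-sum overlap attains its analytic bounds and handles interleaving", {
  grp <- sample_grouping(paste0("s", 1:10), rep(c("T", "O"), c(3, 7)),
                         state_order = c("T", "O"))
  # target strictly above: minimum n_d(n_d+1)/2
  expect_identical(rank_sum_overlap(c(10, 9, 8, 7:1), grp, "T"), 6)
  # target strictly below: maximum
  expect_identical(rank_sum_overlap(c(1, 2, 3, 4:10), grp, "T"), 27)
  # target at descending positions 1, 3, 5
  expect_identical(rank_sum_overlap(c(10, 8, 6, 9, 7, 5, 4, 3, 2, 1), grp, "T"), 9)
  # ties get average ranks, giving half-integer sums
  expect_identical(rank_sum_overlap(c(5, 5, 5, 5, 1, 1, 1, 1, 1, 1), grp, "T"),
                   sum(c(2.5, 2.5, 2.5)))
})

test_that("score ranking puts rank 1 on the most specific gene, ties averaged, NA last", {
  expect_identical(rank_scores(c(0.99, 0.5, 0.7)), c(1, 3, 2))
  expect_identical(rank_scores(c(0.9, 0.9, 0.1)), c(1.5, 1.5, 3))
  expect_identical(rank_scores(c(0.2, NA, 0.8)), c(2, 3, 1))
  expect_identical(rank_scores(c(NA, NA, 0.8)), c(2.5, 2.5, 1))
})

test_that("benchmark cycles are reproducible and expose per-metric rank sums", {
  sim <- sim5()
  bm1 <- run_benchmark(sim$counts, sim$grouping, mode = "multiply",
                       factor = 5, n_induced = 5, n_cycles = 2, seed = 3)
  bm2 <- run_benchmark(sim$counts, sim$grouping, mode = "multiply",
                       factor = 5, n_induced = 5, n_cycles = 2, seed = 3)
  expect_identical(bm1$rank_sums, bm2$rank_sums)
  expect_identical(bm1$detail, bm2$detail)
  expect_identical(dim(bm1$rank_sums), c(2L, 6L))
  expect_identical(colnames(bm1$rank_sums),
                   c("SPECS", "zscore", "JSD", "Gini", "Tau", "TSI"))
  # every rank sum at least the theoretical minimum
  expect_true(all(bm1$rank_sums >= 5 * 6 / 2))
  expect_true(all(bm1$detail$rank_sum_overlap >= 2 * 3 / 2))
})

test_that("strong induction sends induced genes to the top ranks of every metric", {
  sim <- sim5(n_genes = 40)
  bm <- run_benchmark(sim$counts, sim$grouping, mode = "add", factor = 1000,
                      n_induced = 5, n_cycles = 2, seed = 8)
  # ceiling case: each metric's summed rank equals the minimum possible
  expect_true(all(bm$rank_sums == 5 * 6 / 2))
  # identical rank sums across metrics -> no between-metric variance, p = 1
  expect_equal(bm$anova_p, 1)
})

test_that("subsampling at fraction 1 reproduces the full-data scores", {
  sim <- sim5()
  se <- subsample_experiment(sim$counts, sim$grouping, constant = 100,
                             n_induced = 4, fractions = 1, n_repeats = 2,
                             seed = 5)
  # rebuild the induced matrix for repeat 1 and compare
  r1 <- se$scores[se$scores$rep == 1, ]
  ind <- induce_specificity(sim$counts, sim$grouping, unique(r1$gene),
                            r1$target_state[1], mode = "add", factor = 100)
  full <- specs_scores(ind[unique(r1$gene), , drop = FALSE], sim$grouping)
  expect_equal(r1$score, unname(full[r1$gene, r1$target_state[1]]),
               tolerance = 1e-14)
  # perfectly separated genes stay at 1 for every fraction
  se2 <- subsample_experiment(sim$counts, sim$grouping, constant = 1000,
                              n_induced = 3, n_repeats = 2, seed = 6)
  expect_true(all(se2$scores$score == 1))
  expect_equal(se2$anova_p, 1)
  # same seed, same subsamples
  se3 <- subsample_experiment(sim$counts, sim$grouping, constant = 1000,
                              n_induced = 3, n_repeats = 2, seed = 6)
  expect_identical(se2$scores, se3$scores)
  expect_error(subsample_experiment(sim$counts, sim$grouping,
                                    fractions = 0.1, n_induced = 3,
                                    n_repeats = 1, seed = 1),
               "fewer than 2")
})

test_that("fold change to the runner-up state follows the pseudocount rule", {
  expect_identical(fold_change_to_second(c(A = 100, B = 10, C = 5), "A"), 10)
  expect_identical(fold_change_to_second(c(A = 100, B = 0, C = 0), "A",
                                         pseudocount = 1), 101)
  expect_lt(fold_change_to_second(c(A = 10, B = 100, C = 5), "A"), 1)
})
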