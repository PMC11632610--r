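test_that("paired d statistic matches its closed form", {
  m <- rbind(zero = c(0, 0, 0, 0), const = c(0.5, 0.5, 0.5, 0.5),
             hand = c(0.1, 0.3, 0.2, 0.4))
  d <- sam_paired_stat(m, s0 = 0.1)
  expect_equal(unname(d["zero"]), 0)
  expect_equal(unname(d["const"]), 0.5 / 0.1)   # zero variance -> c / s0
  x <- c(0.1, 0.3, 0.2, 0.4)
  expect_equal(unname(sam_paired_stat(m, s0 = 0)["hand"]),
               mean(x) / (sd(x) / sqrt(4)))
  expect_error(sam_paired_stat(matrix(1, 2, 1), 0.1), "2 pairs")
})

test_that("signed fold change follows the +/- 2^m convention", {
  expect_equal(paired_fold_change(0), 1)
  expect_equal(paired_fold_change(1), 2)
  expect_equal(paired_fold_change(0.263), 2^0.263)
  expect_equal(paired_fold_change(0.263), 1.20, tolerance = 0.01)
  expect_equal(paired_fold_change(-1), -2)
  expect_equal(abs(paired_fold_change(c(-0.4, 0, 0.4))) >= 1,
               c(TRUE, TRUE, TRUE))
})

test_that("fudge factor selection behaves on degenerate and two-scale data", {
  set.seed(101)
  expect_warning(s0 <- choose_s0(rnorm(50), rep(0.3, 50)), "identical")
  expect_equal(s0, 0)
  # two variance scales sharing one mean-difference distribution: without a
  # fudge factor the low-variance half dominates |d|, so a positive s0 wins
  s <- c(rep(0.1, 250), rep(1.0, 250))
  r <- rnorm(500, 0, 0.5)
  expect_gt(choose_s0(r, s), 0)
  # a one-point percentile grid is returned verbatim
  expect_equal(choose_s0(r, s, percentiles = 0.5),
               unname(quantile(s, 0.5)))
})

test_that("exhaustive sign-flip q-values equal the brute-force oracle", {
  set.seed(111)
  diffs <- matrix(rnorm(30 * 4, 0, 0.5), 30, 4)
  diffs[1:3, ] <- diffs[1:3, ] + 1.5
  rownames(diffs) <- paste0("g", 1:30)
  res <- sam_permutation_fdr(diffs, sam_config(n_permutations = 16, s0 = 0.2))
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_permutations"), 16)
  orc <- oracle_sam_paired(diffs, s0 = 0.2)
  expect_equal(res$d_stat, unname(orc$d))
  expect_equal(res$q_value, unname(orc$q))
  expect_equal(attr(res, "pi0"), orc$pi0)
})

test_that("sampled permutations approach the exhaustive estimate", {
  set.seed(121)
  diffs <- matrix(rnorm(40 * 10, 0, 0.5), 40, 10)
  diffs[1:4, ] <- diffs[1:4, ] + 1.2
  rownames(diffs) <- paste0("g", 1:40)
  exact <- sam_permutation_fdr(diffs, sam_config(n_permutations = 1024,
                                                 s0 = 0.2))
  sampled <- sam_permutation_fdr(diffs, sam_config(n_permutations = 400,
                                                   s0 = 0.2, seed = 5))
  expect_true(attr(exact, "exhaustive"))
  expect_false(attr(sampled, "exhaustive"))
  expect_equal(sampled$q_value, exact$q_value, tolerance = 0.1)
  expect_identical(which(sampled$q_value <= 0.05), which(exact$q_value <= 0.05))
})

test_that("large planted effects are all called at FDR 5%", {
  set.seed(131)
  diffs <- matrix(rnorm(500 * 12, 0, 0.2), 500, 12)
  diffs[1:20, ] <- diffs[1:20, ] + 1.0
  rownames(diffs) <- paste0("g", 1:500)
  res <- sam_permutation_fdr(diffs, sam_config(n_permutations = 500, seed = 7))
  expect_true(all(res$called[1:20]))
  expect_equal(sum(res$called[-(1:20)]), 0)
  expect_equal(mean(res$fold_change[1:20]), 2, tolerance = 0.1)
})

test_that("d ranks are invariant to rescaling when s0 is re-estimated", {
  set.seed(141)
  diffs <- matrix(rnorm(100 * 8, 0, c(0.2, 1)), 100, 8)
  rownames(diffs) <- paste0("g", 1:100)
  r1 <- sam_permutation_fdr(diffs, sam_config(n_permutations = 100, seed = 3))
  r2 <- sam_permutation_fdr(diffs * 3, sam_config(n_permutations = 100,
                                                  seed = 3))
  expect_equal(attr(r2, "s0"), 3 * attr(r1, "s0"))
  expect_equal(order(r2$d_stat), order(r1$d_stat))
  expect_equal(r2$d_stat, r1$d_stat)
})

test_that("unpaired SAM is antisymmetric and matches its exhaustive oracle", {
  set.seed(151)
  x1 <- matrix(rnorm(40 * 3), 40, 3)
  x2 <- matrix(rnorm(40 * 3), 40, 3)
  x2[1, ] <- x2[1, ] + 5   # 5 sigma shift with sigma = 1
  rownames(x1) <- rownames(x2) <- paste0("g", 1:40)
  cfg <- sam_config(n_permutations = 100, s0 = 0.1)
  res <- sam_unpaired(x1, x2, cfg)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_permutations"), choose(6, 3))
  expect_equal(res$gene_id[which.max(abs(res$d_stat))], "g1")
  orc <- oracle_sam_unpaired(x1, x2, s0 = 0.1)
  expect_equal(res$d_stat, unname(orc$d), tolerance = 1e-12)
  expect_equal(res$q_value, unname(orc$q), tolerance = 1e-12)
  # swapping the groups negates d and preserves |d| and q
  swp <- sam_unpaired(x2, x1, cfg)
  expect_equal(swp$d_stat, -res$d_stat, tolerance = 1e-12)
  expect_equal(swp$q_value, res$q_value, tolerance = 1e-12)
  # identical groups give d = 0 and no calls
  same <- sam_unpaired(x1, x1, sam_config(n_permutations = 100, s0 = 0.1))
  expect_lt(max(abs(same$d_stat)), 1e-10)
  expect_false(any(same$called))
  expect_error(sam_unpaired(x1[, 1, drop = FALSE], x2, cfg), "2 samples")
})

test_that("configuration guards reject unusable settings", {
  expect_error(sam_config(n_permutations = 5), "n_permutations")
  expect_error(sam_config(fc_threshold = 0.5), "fc_threshold")
  expect_error(sam_config(fdr_target = 0), "fdr_target")
})
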