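test_that("per-study correlation matches the direct covariance formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 3.8)
  m <- matrix(y, 1, 4, dimnames = list("g1", NULL))
  out <- per_study_association(m, x, "s1")
  expect_equal(out$r, oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(out$n, 4)
  # p consistent with the t transform
  tt <- out$r * sqrt(2) / sqrt(1 - out$r^2)
  expect_equal(out$p, 2 * pt(abs(tt), 2, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("perfect and orthogonal relations hit the r extremes", {
  llm <- c(-2, -1, 0, 1, 2)
  exact <- matrix(2 * llm, 1, 5, dimnames = list("lin", NULL))
  expect_equal(per_study_association(exact, llm)$r, 1)
  expect_lt(per_study_association(exact, llm)$p, 1e-10)
  orth <- matrix(c(1, -1, 0, -1, 1), 1, 5, dimnames = list("o", NULL))
  out <- per_study_association(orth, llm)
  expect_equal(out$r, 0)
  expect_equal(out$p, 1)
  # zero-variance gene flagged with NA
  flat <- matrix(1, 1, 5, dimnames = list("flat", NULL))
  expect_true(is.na(per_study_association(flat, llm)$r))
  expect_error(per_study_association(exact[, 1:2, drop = FALSE], llm[1:2]),
               "3 subjects")
})

test_that("Stouffer pooling matches its closed forms", {
  expect_equal(stouffer_pool(0.2, 1), 0.2, tolerance = 1e-12)
  # null inputs (p = 1 so z = 0) pool to the two-sided p of Z = 0
  expect_equal(stouffer_pool(rep(1, 3), rep(1, 3)), 1, tolerance = 1e-12)
  # equal evidence in opposite directions cancels exactly
  expect_equal(stouffer_pool(c(0.5, 0.5), c(1, -1)), 1, tolerance = 1e-12)
  # three studies at |z| = 2, all positive: Z = 2*sqrt(3)
  p2 <- 2 * pnorm(2, lower.tail = FALSE)
  pooled <- stouffer_pool(rep(p2, 3), rep(1, 3))
  expect_equal(pooled, 2 * pnorm(2 * sqrt(3), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(pooled, 5.32e-4, tolerance = 1e-2)
})

test_that("Stouffer pooling is symmetric and direction-reversible", {
  set.seed(161)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    p <- runif(k)
    sg <- sample(c(-1, 1), k, replace = TRUE)
    perm <- sample(k)
    expect_equal(stouffer_pool(p, sg), stouffer_pool(p[perm], sg[perm]))
    expect_equal(stouffer_pool(p, sg), stouffer_pool(p, -sg))
  }
  expect_warning(z <- stouffer_pool(c(0, 0.5), c(1, 1)), "clipped")
  expect_true(z >= 0 && z <= 1)
})

test_that("BH adjustment matches the step-up oracle and its bounds", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(171)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  }
})

test_that("association filters follow the published three-filter rule", {
  # per-study r patterns from hand-constructed data are hard to force
  # exactly, so the filters are exercised on synthetic association rows
  mk <- function(gene, rs, ns = c(32, 33, 47, 20, 12)) {
    tt <- rs * sqrt(ns - 2) / sqrt(1 - rs^2)
    data.frame(gene_id = gene, study_id = paste0("study", 1:5), r = rs,
               p = 2 * pt(abs(tt), ns - 2, lower.tail = FALSE), n = ns)
  }
  a <- rbind(mk("pass_i_ii", c(0.3, 0.25, -0.1, 0.22, 0.28)),
             mk("fail_i", c(0.1, 0.1, 0.1, 0.1, 0.1)),
             mk("fail_ii", c(0.3, 0.3, -0.3, -0.3, 0.25)))
  out <- apply_association_filters(a)
  row <- function(g) out[out$gene_id == g, ]
  expect_true(row("pass_i_ii")$pass_median_r)
  expect_true(row("pass_i_ii")$pass_direction)
  expect_equal(row("pass_i_ii")$n_consistent, 4)
  expect_false(row("fail_i")$pass_median_r)
  expect_false(row("fail_ii")$pass_direction)
  expect_true(is.na(row("fail_i")$fdr))   # BH only over filter i&ii survivors
  # the three largest studies are pooled (ties broken by study id)
  expect_equal(attr(out, "pooled_studies"), c("study3", "study2", "study1"))
})

test_that("conditional BH equals a brute-force BH over the survivors", {
  set.seed(181)
  n_sub <- 30
  llm <- rnorm(n_sub, 3, 4)
  expr <- matrix(rnorm(100 * n_sub, 0, 0.7), 100, n_sub,
                 dimnames = list(sprintf("g%03d", 1:100), NULL))
  expr[1:10, ] <- expr[1:10, ] + outer(rep(0.1, 10), llm)  # r ~ 0.5
  assoc <- do.call(rbind, lapply(1:5, function(st) {
    idx <- ((st - 1) * 6 + 1):(st * 6)   # 5 pseudo-studies of 6 subjects
    per_study_association(expr[, idx], llm[idx], paste0("study", st))
  }))
  out <- apply_association_filters(assoc, fdr_max = 0.2)
  cand <- out$pass_median_r & out$pass_direction
  expect_equal(out$fdr[cand], oracle_bh(out$pooled_p[cand]), tolerance = 1e-12)
  expect_true(all(is.na(out$fdr[!cand])))
  expect_identical(out$passed, cand & !is.na(out$fdr) & out$fdr < 0.2)
})

test_that("genes with an undefined study r are excluded, not imputed", {
  llm <- c(1, 2, 3, 4, 5)
  good <- matrix(rnorm(10), 2, 5, dimnames = list(c("a", "b"), NULL))
  assoc <- do.call(rbind, lapply(1:5, function(st) {
    m <- good
    if (st == 3) m["b", ] <- 1   # zero variance in one study
    per_study_association(m, llm, paste0("study", st))
  }))
  out <- apply_association_filters(assoc)
  expect_false("b" %in% out$gene_id)
  expect_true("b" %in% attr(out, "excluded"))
  expect_true("a" %in% out$gene_id)
})
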