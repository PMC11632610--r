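test_that("planarity test pins the classical graph families", {
  k4 <- t(combn(4, 2)); k5 <- t(combn(5, 2))
  k33 <- as.matrix(expand.grid(1:3, 4:6))
  expect_true(is_planar(k4, 4))
  expect_false(is_planar(k5, 5))
  expect_false(is_planar(k33, 6))
  # K5 minus any single edge is planar
  for (i in seq_len(nrow(k5))) expect_true(is_planar(k5[-i, ], 5))
  # Petersen graph is non-planar
  pet <- rbind(cbind(1:5, c(2:5, 1)), cbind(1:5, 6:10),
               cbind(6:10, c(8, 9, 10, 6, 7)))
  expect_false(is_planar(pet, 10))
  # planar grid stays planar; gluing K5 onto it does not
  k <- 6; id <- function(i, j) (i - 1) * k + j
  grid_e <- NULL
  for (i in 1:k) for (j in 1:k) {
    if (j < k) grid_e <- rbind(grid_e, c(id(i, j), id(i, j + 1)))
    if (i < k) grid_e <- rbind(grid_e, c(id(i, j), id(i + 1, j)))
  }
  expect_true(is_planar(grid_e, k * k))
  expect_false(is_planar(rbind(grid_e, t(combn(5, 2)) + k * k), k * k + 5))
  # disconnected components are tested independently
  two_k4 <- rbind(k4, k4 + 4)
  expect_true(is_planar(two_k4, 8))
  expect_false(is_planar(rbind(k5, k5 + 5), 10))
  expect_true(is_planar(matrix(integer(0), 0, 2), 5))
})

test_that("edge significance follows the t transform exactly", {
  set.seed(241)
  expr <- matrix(rnorm(10 * 50), 10, 50,
                 dimnames = list(paste0("g", 1:10), NULL))
  expr["g2", ] <- expr["g1", ] + rnorm(50, 0, 0.1)
  edges <- significant_edges(expr, edge_fdr_max = 0.05)
  top <- edges[1, ]
  expect_setequal(c(top$gene_a, top$gene_b), c("g1", "g2"))
  # p matches cor.test to numerical precision
  for (i in seq_len(nrow(edges))) {
    ct <- cor.test(expr[edges$gene_a[i], ], expr[edges$gene_b[i], ])
    expect_equal(edges$p[i], ct$p.value, tolerance = 1e-10)
    expect_equal(edges$r[i], unname(ct$estimate), tolerance = 1e-12)
  }
})

test_that("duplicated genes always yield a retained |r| = 1 edge", {
  set.seed(251)
  expr <- matrix(rnorm(5 * 40), 5, 40, dimnames = list(paste0("g", 1:5), NULL))
  expr["g5", ] <- expr["g4", ]
  e <- significant_edges(expr, edge_fdr_max = 0.01)
  dup <- e[e$gene_a == "g4" & e$gene_b == "g5", ]
  expect_equal(nrow(dup), 1)
  expect_equal(dup$weight, 1)
})

test_that("null matrices retain edges at no more than the calibration bound", {
  set.seed(261)
  expr <- matrix(rnorm(500 * 100), 500, 100,
                 dimnames = list(sprintf("g%03d", 1:500), NULL))
  e <- significant_edges(expr, edge_fdr_max = 0.01)
  n_pairs <- choose(500, 2)
  bound <- 0.01 * n_pairs * 2 + 3 * sqrt(0.01 * n_pairs)
  expect_lte(nrow(e), bound)
})

test_that("planted modules are recovered as dense edge blocks", {
  co <- generate_network_cohort(sim_config(module_rho = 0.8, seed = 271))
  mem <- co$truth$module_memberships[[1]]
  others <- setdiff(unlist(co$truth$module_memberships), mem)[1:30]
  e <- significant_edges(co$expr[c(mem, others), ], edge_fdr_max = 0.01)
  within <- e$gene_a %in% mem & e$gene_b %in% mem
  cross <- xor(e$gene_a %in% mem, e$gene_b %in% mem)
  expect_equal(sum(within), choose(length(mem), 2))   # all within retained
  expect_lt(sum(cross), 0.01 * length(mem) * 30 + 10) # cross ~ null rate
})

test_that("PFN construction drops the minimum-weight K5 edge and only it", {
  k5 <- t(combn(5, 2))
  set.seed(281)
  w <- sample(seq(0.5, 0.95, length.out = 10))
  edges <- data.frame(gene_a = paste0("n", k5[, 1]),
                      gene_b = paste0("n", k5[, 2]), weight = w)
  g <- build_pfn(edges)
  expect_equal(igraph::ecount(g), 9)
  dropped <- edges[order(edges$weight), ][1, ]
  expect_equal(igraph::ecount(g), nrow(edges) - 1)
  expect_false(igraph::are_adjacent(g, dropped$gene_a, dropped$gene_b))
  # K4: all six edges survive; empty input gives an empty graph
  k4 <- t(combn(4, 2))
  g4 <- build_pfn(data.frame(gene_a = paste0("n", k4[, 1]),
                             gene_b = paste0("n", k4[, 2]),
                             weight = seq(0.9, 0.4, length.out = 6)))
  expect_equal(igraph::ecount(g4), 6)
  g0 <- build_pfn(data.frame(gene_a = character(), gene_b = character(),
                             weight = numeric()))
  expect_equal(igraph::ecount(g0), 0)
})

test_that("PFN respects the planar edge bound on random graphs", {
  set.seed(291)
  for (n in c(12, 40, 200)) {
    nodes <- sprintf("v%03d", 1:n)
    m <- min(3 * n + 40, choose(n, 2))
    pairs <- t(combn(n, 2))[sample(choose(n, 2), m), , drop = FALSE]
    edges <- data.frame(gene_a = nodes[pmin(pairs[, 1], pairs[, 2])],
                        gene_b = nodes[pmax(pairs[, 1], pairs[, 2])],
                        weight = runif(m))
    g <- build_pfn(edges)
    expect_lte(igraph::ecount(g), 3 * n - 6)
    el <- igraph::as_edgelist(g, names = FALSE)
    expect_true(is_planar(el, igraph::vcount(g)))
  }
})

test_that("PFN is invariant to input edge order under distinct weights", {
  set.seed(301)
  n <- 25
  pairs <- t(combn(n, 2))
  m <- 120
  sel <- pairs[sample(nrow(pairs), m), ]
  edges <- data.frame(gene_a = sprintf("v%02d", sel[, 1]),
                      gene_b = sprintf("v%02d", sel[, 2]),
                      weight = sample(seq(0.01, 0.99, length.out = m)))
  g1 <- build_pfn(edges)
  g2 <- build_pfn(edges[sample(nrow(edges)), ])
  e1 <- igraph::as_edgelist(g1); e2 <- igraph::as_edgelist(g2)
  key <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_identical(key(e1), key(e2))
})

test_that("module statistics report composition, expression and hubs", {
  nodes <- sprintf("m%02d", 1:10)
  star <- data.frame(gene_a = nodes[1], gene_b = nodes[2:10],
                     weight = seq(0.9, 0.5, length.out = 9))
  g <- build_pfn(star)
  catalog <- data.frame(gene_id = nodes,
                        biotype = c(rep("protein_coding", 9), "lncRNA"))
  expr <- matrix(rep(c(3, 4, 5), length.out = 10 * 6), 10, 6,
                 dimnames = list(nodes, NULL))
  st <- module_stats(nodes, g, expr, catalog, hub_degree_quantile = 0.95)
  expect_equal(unname(st$biotype_composition),
               c(90, 10, 0, 0))
  expect_equal(sum(st$biotype_composition), 100)
  expect_equal(st$hubs, nodes[1])    # star centre is the unique hub
  # median over members of per-gene medians
  expr3 <- rbind(a = rep(3, 4), b = rep(4, 4), c = rep(5, 4))
  g3 <- build_pfn(data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                             weight = c(0.9, 0.8)))
  cat3 <- data.frame(gene_id = c("a", "b", "c"), biotype = "lncRNA")
  expect_equal(module_stats(c("a", "b", "c"), g3, expr3, cat3)$median_expression,
               4)
  expect_error(module_stats(nodes, g, expr, catalog[-1, ]), "absent")
})

test_that("candidate lookup filters by membership and size", {
  mods <- list(A = letters[1:4], B = letters[5:8], C = letters[9:12],
               D = letters[c(1, 13:18)], E = letters[19:22])
  hits <- candidate_module_lookup(c("a", "f"), mods)
  expect_setequal(names(hits), c("A", "B", "D"))
  expect_equal(attr(hits$A, "contains_candidates"), "a")
  expect_length(candidate_module_lookup("zz", mods), 0)
  # strict size bound mirrors the "< 500 genes" module selection
  sized <- list(s60 = paste0("x", 1:60), s600 = c("a", paste0("y", 1:599)))
  keep <- candidate_module_lookup(c("x1", "a"), sized, size_max = 500)
  expect_setequal(names(keep), "s60")
})

test_that("PFN clustering produces k covering modules", {
  co <- generate_network_cohort(sim_config(module_rho = 0.8, seed = 311))
  genes <- unlist(co$truth$module_memberships)
  e <- significant_edges(co$expr[genes, ], edge_fdr_max = 0.01)
  g <- build_pfn(e)
  mods <- pfn_modules(g, k = 5)
  expect_length(mods, 5)
  expect_setequal(unlist(mods), igraph::V(g)$name)
  # planted blocks should be largely reconstructed
  overlap <- vapply(co$truth$module_memberships, function(mem) {
    max(vapply(mods, function(m) length(intersect(m, mem)), numeric(1)))
  }, numeric(1)) / lengths(co$truth$module_memberships)
  expect_gt(mean(overlap), 0.8)
})
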