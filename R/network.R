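#' FDR-thresholded co-expression edges
#'
#' Scores every gene pair by Pearson correlation across samples, converts to
#' two-sided p-values through the t transform, adjusts across all pairs with
#' Benjamini-Hochberg, and keeps pairs below `edge_fdr_max`. Zero-variance
#' genes are excluded before pairing. A permutation mode is available for
#' p-value calibration: each gene's sample order is shuffled independently
#' `n_permutations` times and the pooled null |r| distribution supplies
#' empirical p-values.
#'
#' @param expr numeric matrix genes x samples (log2), rownames = gene ids.
#' @param edge_fdr_max FDR threshold for retaining an edge.
#' @param method `"parametric"` (t transform, default) or `"permutation"`.
#' @param n_permutations resamples of the global null in permutation mode.
#' @param seed seed for permutation mode.
#' @return data.frame `gene_a, gene_b, r, p, fdr, weight` (weight = |r|)
#'   for retained edges, sorted by descending weight.
#' @export
significant_edges <- function(expr, edge_fdr_max = 0.01,
                              method = c("parametric", "permutation"),
                              n_permutations = 1000, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  n <- ncol(expr)
  if (n < 30) stop("need at least 30 samples for edge estimation")
  v <- apply(expr, 1, stats::var)
  expr <- expr[v > 0, , drop = FALSE]
  G <- nrow(expr)
  if (G < 2) stop("fewer than 2 genes with variance")
  cm <- stats::cor(t(expr))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  if (method == "parametric") {
    tt <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  } else {
    set.seed(seed)
    pool_size <- min(length(r), 2000L)
    null_r <- unlist(lapply(seq_len(n_permutations), function(b) {
      shuf <- t(apply(expr, 1, sample))
      idx <- matrix(sample.int(G, 2 * pool_size %/% n_permutations + 2),
                    ncol = 2)
      idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
      vapply(seq_len(nrow(idx)), function(i)
        stats::cor(shuf[idx[i, 1], ], shuf[idx[i, 2], ]), numeric(1))
    }))
    null_abs <- sort(abs(null_r))
    p <- (length(null_abs) -
            findInterval(abs(r), null_abs, left.open = TRUE) + 1) /
         (length(null_abs) + 1)
  }
  fdr <- benjamini_hochberg(p)
  keep <- fdr < edge_fdr_max
  out <- data.frame(gene_a = rownames(expr)[ut[keep, 1]],
                    gene_b = rownames(expr)[ut[keep, 2]],
                    r = r[keep], p = p[keep], fdr = fdr[keep],
                    weight = abs(r[keep]), stringsAsFactors = FALSE)
  out[order(-out$weight, out$gene_a, out$gene_b), ]
}

#' Planar maximally filtered network
#'
#' Greedy construction of the planar maximally filtered graph: edges are
#' inserted in descending weight (ties broken lexicographically by endpoint
#' labels) and an edge is kept only when the graph stays planar after
#' insertion. The result has at most `3V - 6` edges and is itself planar;
#' both facts are asserted on every build.
#'
#' @param edges data.frame with `gene_a`, `gene_b` and `weight` columns
#'   (weights in `[0, 1]`), e.g. from [significant_edges()].
#' @param nodes optional character vector of node names to include even when
#'   isolated; defaults to the endpoints observed in `edges`.
#' @return an `igraph` graph with edge attribute `weight`.
#' @export
build_pfn <- function(edges, nodes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (nrow(edges) && (any(edges$weight < 0) || any(edges$weight > 1)))
    stop("edge weights must lie in [0, 1]")
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (!nrow(edges)) return(g)
  edges <- edges[order(-edges$weight, edges$gene_a, edges$gene_b), ]
  ia <- match(edges$gene_a, nodes)
  ib <- match(edges$gene_b, nodes)
  V <- length(nodes)
  max_edges <- if (V >= 3) 3L * V - 6L else choose(V, 2)
  acc <- matrix(integer(0), ncol = 2)
  acc_w <- numeric(0)
  for (i in seq_len(nrow(edges))) {
    if (nrow(acc) >= max_edges) break
    cand <- rbind(acc, c(ia[i], ib[i]))
    if (nrow(cand) <= 8 || is_planar(cand, V)) {
      acc <- cand
      acc_w <- c(acc_w, edges$weight[i])
    }
  }
  stopifnot(nrow(acc) <= max_edges, is_planar(acc, V))
  g <- igraph::add_edges(g, t(acc), weight = acc_w)
  g
}

#' Stand-in module memberships from a planar filtered network
#'
#' Connected components of the planar filtered network are taken as modules;
#' while fewer than `k` modules exist, the largest one is bisected by
#' average-linkage agglomerative clustering on its internal shortest-path
#' distance, with each edge costed `1 - |r|` so that strongly co-expressed
#' neighbours are close and chance bridges between blocks are expensive.
#' This is a documented stand-in used when module memberships are not
#' supplied externally. When the network has more than `k` components,
#' every component is returned (no merging is invented).
#'
#' @param pfn an `igraph` graph from [build_pfn()].
#' @param k target number of modules.
#' @return named list of character vectors (module id -> member gene ids),
#'   ordered by decreasing size.
#' @export
pfn_modules <- function(pfn, k) {
  stopifnot(igraph::vcount(pfn) >= k, k >= 1)
  comp <- igraph::components(pfn)
  groups <- unname(split(igraph::V(pfn)$name, comp$membership))
  while (length(groups) < k) {
    i <- which.max(lengths(groups))
    if (length(groups[[i]]) < 2) break
    sub <- igraph::induced_subgraph(pfn, groups[[i]])
    w <- igraph::E(sub)$weight
    d <- igraph::distances(sub, weights = if (is.null(w)) NULL else 1 - w)
    d[!is.finite(d)] <- max(d[is.finite(d)]) + 1
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, k = 2)
    groups <- c(groups[-i], unname(split(groups[[i]], cl)))
  }
  groups <- groups[order(-lengths(groups))]
  names(groups) <- sprintf("M%02d", seq_along(groups))
  groups
}

#' Module statistics: biotype composition, median expression, hubs
#'
#' @param members character vector of module gene ids (must be graph nodes).
#' @param pfn the planar filtered network (`igraph`).
#' @param expr expression matrix genes x samples (log2).
#' @param catalog gene catalog with `gene_id`, `biotype`.
#' @param hub_degree_quantile hubs are members at or above this quantile of
#'   within-module degree.
#' @return list with `members`, `hubs`, `biotype_composition` (percent per
#'   class, sums to 100), `median_expression` (median over members of the
#'   per-gene median log2 signal), `size`.
#' @export
module_stats <- function(members, pfn, expr, catalog,
                         hub_degree_quantile = 0.9) {
  stopifnot(all(members %in% igraph::V(pfn)$name))
  missing_cat <- setdiff(members, catalog$gene_id)
  if (length(missing_cat))
    stop("members absent from catalog: ", paste(missing_cat, collapse = ", "))
  sub <- igraph::induced_subgraph(pfn, members)
  deg <- igraph::degree(sub)
  hubs <- names(deg)[deg >= stats::quantile(deg, hub_degree_quantile)]
  bt <- catalog$biotype[match(members, catalog$gene_id)]
  lev <- c("protein_coding", "lncRNA", "miscRNA", "pseudogene")
  comp <- 100 * vapply(lev, function(b) mean(bt == b), numeric(1))
  med <- NA_real_
  present <- intersect(members, rownames(expr))
  if (length(present))
    med <- stats::median(apply(expr[present, , drop = FALSE], 1, stats::median))
  list(members = members, hubs = hubs, biotype_composition = comp,
       median_expression = med, size = length(members))
}

#' Modules containing at least one signature candidate
#'
#' @param signature character vector of candidate gene ids.
#' @param modules named list of member-gene vectors.
#' @param size_max optional strict upper size bound (modules with
#'   `size >= size_max` are dropped), mirroring the "< 500 genes" selection.
#' @return named list of the retained modules, each with attribute
#'   `"contains_candidates"` listing its candidates.
#' @export
candidate_module_lookup <- function(signature, modules, size_max = NULL) {
  keep <- lapply(modules, function(mem) {
    cand <- intersect(mem, signature)
    if (!length(cand)) return(NULL)
    if (!is.null(size_max) && length(mem) >= size_max) return(NULL)
    attr(mem, "contains_candidates") <- cand
    mem
  })
  keep[!vapply(keep, is.null, logical(1))]
}

#' Pairwise Jaccard overlap between module gene sets
#'
#' @param modules named list of member-gene vectors.
#' @return data.frame `module_a, module_b, jaccard`.
#' @export
module_jaccard <- function(modules) {
  nm <- names(modules)
  if (length(nm) < 2)
    return(data.frame(module_a = character(), module_b = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE))
  pairs <- utils::combn(nm, 2)
  data.frame(
    module_a = pairs[1, ], module_b = pairs[2, ],
    jaccard = apply(pairs, 2, function(pr) {
      a <- modules[[pr[1]]]; b <- modules[[pr[2]]]
      length(intersect(a, b)) / length(union(a, b))
    }),
    stringsAsFactors = FALSE
  )
}
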