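#' Over-representation analysis against a custom background
#'
#' For each term set, the overlap with the module gene list is tested with
#' the upper-tail hypergeometric probability `P(X >= k)` given background
#' size `N`, term size `K` (restricted to the background) and module size
#' `n`, and summarised as fold enrichment `FE = (k/n) / (K/N)`. P-values are
#' BH-adjusted across the terms tested in the call. Module genes outside the
#' background are dropped (their count is recorded), mirroring the usual
#' loss of unmapped identifiers. With `ease = TRUE` the more conservative
#' EASE variant (k reduced by one) is used.
#'
#' @param module_genes character vector of gene ids.
#' @param terms named list of character vectors (term id -> gene set).
#' @param background character vector of background gene ids (non-empty).
#' @param ease use the EASE-adjusted score.
#' @return data.frame `term_id, overlap_k, module_n, term_K, background_N,
#'   fold_enrichment, p, fdr`, sorted by p; attribute `"n_unmapped"` counts
#'   module genes outside the background.
#' @export
ora <- function(module_genes, terms, background, ease = FALSE) {
  stopifnot(is.list(terms), length(terms) > 0, !is.null(names(terms)))
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  module_genes <- unique(as.character(module_genes))
  unmapped <- sum(!(module_genes %in% background))
  mod <- intersect(module_genes, background)
  N <- length(background)
  n <- length(mod)
  rows <- lapply(names(terms), function(tid) {
    tg <- intersect(unique(terms[[tid]]), background)
    K <- length(tg)
    k <- length(intersect(mod, tg))
    fe <- if (k == 0 || n == 0 || K == 0) 0 else (k / n) / (K / N)
    kk <- if (ease) max(k - 1, 0) else k
    p <- if (K == 0 || n == 0) 1 else
      stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, overlap_k = k, module_n = n, term_K = K,
               background_N = N, fold_enrichment = fe, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- benjamini_hochberg(out$p)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- unmapped
  out
}

#' Select modules by size and best term FDR
#'
#' Retains modules that are strictly smaller than `size_max` genes and reach
#' an FDR at or below `fdr_max` for at least one term.
#'
#' @param results named list of [ora()] tables, one per module.
#' @param sizes named integer vector of module sizes (same names).
#' @param fdr_max maximum best-term FDR (default 5e-5).
#' @param size_max strict module-size bound (default 500).
#' @return character vector of retained module names.
#' @export
select_enriched_modules <- function(results, sizes, fdr_max = 5e-5,
                                    size_max = 500) {
  stopifnot(all(names(results) %in% names(sizes)))
  keep <- vapply(names(results), function(nm) {
    res <- results[[nm]]
    sizes[[nm]] < size_max && nrow(res) > 0 && min(res$fdr) <= fdr_max
  }, logical(1))
  names(results)[keep]
}
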