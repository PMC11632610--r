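#' SAM analysis configuration
#'
#' Settings for the Significance Analysis of Microarrays runs: number of
#' permutations (exhaustive enumeration is used automatically whenever the
#' design allows fewer arrangements than requested), the FDR target, the
#' signed fold-change threshold, the percentile grid scanned for the fudge
#' factor s0, and the seed controlling permutation sampling.
#'
#' @param n_permutations permutations for the null distribution (>= 10).
#' @param fdr_target q-value cut-off for calling a gene (proportion).
#' @param fc_threshold minimum absolute signed fold change (linear scale,
#'   >= 1).
#' @param s0_percentiles percentile grid scanned by [choose_s0()].
#' @param s0 optional fixed fudge factor; when `NULL` it is estimated.
#' @param n_delta number of evenly spaced thresholds between 0 and max |d|.
#' @param fc_mode `"joint"` applies the fold-change filter inside the call
#'   (q and FC as a conjunction); `"posthoc"` calls on q alone and reports
#'   the FC filter as a separate column.
#' @param seed integer seed for permutation sampling.
#' @return list of class `sam_config`.
#' @export
sam_config <- function(n_permutations = 1000, fdr_target = 0.05,
                       fc_threshold = 1.2, s0_percentiles = seq(0, 1, 0.05),
                       s0 = NULL, n_delta = 200,
                       fc_mode = c("joint", "posthoc"), seed = 1L) {
  stopifnot(n_permutations >= 10, fdr_target > 0, fdr_target < 1,
            fc_threshold >= 1, n_delta >= 2)
  structure(list(n_permutations = as.integer(n_permutations),
                 fdr_target = fdr_target, fc_threshold = fc_threshold,
                 s0_percentiles = s0_percentiles, s0 = s0, n_delta = n_delta,
                 fc_mode = match.arg(fc_mode), seed = as.integer(seed)),
            class = "sam_config")
}

#' Paired SAM statistic
#'
#' The moderated paired statistic `d = mean(diff) / (s + s0)` per gene, where
#' `diff` is the per-subject post minus pre log2 difference and
#' `s = sd(diff) / sqrt(n)` is its standard error. The fudge factor `s0`
#' stabilises genes with very small variance.
#'
#' @param diffs numeric matrix genes x pairs of log2 differences.
#' @param s0 non-negative fudge factor.
#' @return numeric vector of d statistics (named by rownames).
#' @export
sam_paired_stat <- function(diffs, s0) {
  stopifnot(is.matrix(diffs), s0 >= 0)
  if (ncol(diffs) < 2) stop("need at least 2 pairs per gene")
  n <- ncol(diffs)
  m <- rowMeans(diffs)
  s <- sqrt((rowSums(diffs^2) - n * m^2) / (n - 1)) / sqrt(n)
  d <- m / (s + s0)
  names(d) <- rownames(diffs)
  d
}

#' Signed linear-scale fold change from paired log2 differences
#'
#' Mean log2 difference `m` mapped to the signed convention: `2^m` for
#' upregulation, `-2^(-m)` for downregulation (so -1.2 means 1.2-fold down
#' and |FC| is always >= 1).
#'
#' @param diffs matrix genes x pairs of log2 differences, or a numeric
#'   vector of mean log2 differences.
#' @return numeric vector of signed fold changes.
#' @export
paired_fold_change <- function(diffs) {
  m <- if (is.matrix(diffs)) rowMeans(diffs) else diffs
  ifelse(m >= 0, 2^m, -(2^(-m)))
}

#' Choose the SAM fudge factor s0
#'
#' Scans candidate s0 values (percentiles of the per-gene standard errors)
#' and picks the one minimising the coefficient of variation of the median
#' absolute deviation of d computed within windows of genes grouped by their
#' standard-error quantile (the Tusher/Chu procedure). Ties resolve to the
#' smallest candidate.
#'
#' @param mean_diff per-gene numerators (mean differences).
#' @param s per-gene standard errors.
#' @param percentiles percentile grid for the candidates.
#' @return chosen s0 (scalar); 0 with a warning when all `s` are equal.
#' @export
choose_s0 <- function(mean_diff, s, percentiles = seq(0, 1, 0.05)) {
  stopifnot(length(mean_diff) == length(s))
  if (length(s) < 20) stop("need at least 20 genes to estimate s0")
  if (stats::sd(s) == 0) {
    warning("all standard errors identical; s0 set to 0")
    return(0)
  }
  candidates <- stats::quantile(s, percentiles, names = FALSE)
  if (length(candidates) == 1) return(candidates)
  ngroups <- min(100L, max(5L, length(s) %/% 5L))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = ngroups + 1)))
  grp <- cut(s, br, include.lowest = TRUE)
  cv <- vapply(candidates, function(s0) {
    dd <- mean_diff / (s + s0)
    mads <- tapply(dd, grp, stats::mad)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  ord <- order(cv, candidates)
  candidates[ord[1]]
}

# all +/-1 sign vectors (or a seeded sample without replacement) as n x B
.sign_matrix <- function(n, n_permutations, seed) {
  total <- 2^n
  if (n <= 30 && total <= n_permutations) {
    codes <- 0:(total - 1)
  } else if (n <= 30) {
    set.seed(seed)
    codes <- sample.int(total, n_permutations) - 1
  } else {
    set.seed(seed)
    return(matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE),
                  nrow = n))
  }
  vapply(codes, function(code)
    ifelse(bitwAnd(code, 2^(0:(n - 1))) > 0, -1, 1), numeric(n))
}

# shared permutation-FDR machinery: per-threshold median false calls, pi0,
# per-gene q-values by SAM's convention
.sam_fdr <- function(d, d_perm, n_delta, fdr_target) {
  abs_d <- abs(d)
  grid <- seq(0, max(abs_d), length.out = n_delta)
  sorted_obs <- sort(abs_d)
  n_called <- length(d) - findInterval(grid, sorted_obs, left.open = TRUE)
  counts <- vapply(seq_len(ncol(d_perm)), function(b) {
    sb <- sort(abs(d_perm[, b]))
    length(sb) - findInterval(grid, sb, left.open = TRUE)
  }, numeric(length(grid)))
  med_null <- apply(counts, 1, stats::median)
  qs <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, mean(d_perm >= qs[1] & d_perm <= qs[2]) / 0.5)
  fdr_grid <- pmin(1, pi0 * med_null / pmax(n_called, 1))
  run_min <- cummin(fdr_grid)
  q <- run_min[findInterval(abs_d, grid)]
  idx <- which(fdr_grid <= fdr_target)
  delta <- if (length(idx)) grid[min(idx)] else NA_real_
  list(q = q, pi0 = pi0, delta = delta, grid = grid, fdr_grid = fdr_grid,
       n_called = n_called, med_null = med_null)
}

.sam_result <- function(gene_id, d, m, s, s0, fdrinfo, config, n_perm_used,
                        exhaustive) {
  fc <- paired_fold_change(m)
  fc_pass <- abs(fc) >= config$fc_threshold
  called <- if (config$fc_mode == "joint")
    fdrinfo$q <= config$fdr_target & fc_pass
  else fdrinfo$q <= config$fdr_target
  out <- data.frame(gene_id = gene_id, d_stat = d, mean_diff = m, s = s,
                    fold_change = fc, q_value = fdrinfo$q,
                    fc_pass = fc_pass, called = called,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "s0") <- s0
  attr(out, "pi0") <- fdrinfo$pi0
  attr(out, "delta") <- fdrinfo$delta
  attr(out, "fdr_grid") <- data.frame(delta = fdrinfo$grid,
                                      fdr = fdrinfo$fdr_grid,
                                      n_called = fdrinfo$n_called,
                                      median_null_called = fdrinfo$med_null)
  attr(out, "n_permutations") <- n_perm_used
  attr(out, "exhaustive") <- exhaustive
  out
}

#' Paired SAM with sign-flip permutation FDR
#'
#' Full paired two-class (pre/post) SAM analysis: fudge-factor estimation,
#' observed d statistics, a null distribution from sign-flipping each
#' subject's difference vector (exhaustive over all 2^n flips whenever that
#' is no more than the requested number of permutations, otherwise a seeded
#' sample without replacement), SAM's median-false-positive FDR estimate on
#' a symmetric |d| >= delta grid with pi0 estimated from the permuted d
#' falling in the observed interquartile range, and per-gene q-values (the
#' smallest estimated FDR at which the gene is called).
#'
#' @param diffs numeric matrix genes x pairs of post minus pre log2
#'   differences, rownames = gene ids.
#' @param config a [sam_config()].
#' @return data.frame `gene_id, d_stat, mean_diff, s, fold_change, q_value,
#'   fc_pass, called`, with attributes `s0`, `pi0`, `delta` (smallest
#'   threshold meeting the FDR target), `fdr_grid`, `n_permutations`,
#'   `exhaustive`.
#' @export
sam_permutation_fdr <- function(diffs, config = sam_config()) {
  stopifnot(is.matrix(diffs), inherits(config, "sam_config"))
  if (ncol(diffs) < 2) stop("need at least 2 pairs")
  n <- ncol(diffs)
  m <- rowMeans(diffs)
  s <- sqrt(pmax(rowSums(diffs^2) - n * m^2, 0) / (n - 1)) / sqrt(n)
  s0 <- if (is.null(config$s0)) choose_s0(m, s, config$s0_percentiles)
        else config$s0
  d <- m / (s + s0)

  signs <- .sign_matrix(n, config$n_permutations, config$seed)
  mean_b <- (diffs %*% signs) / n
  ss <- rowSums(diffs^2)
  var_b <- pmax(ss - n * mean_b^2, 0) / (n - 1)
  d_perm <- mean_b / (sqrt(var_b / n) + s0)

  fdrinfo <- .sam_fdr(d, d_perm, config$n_delta, config$fdr_target)
  .sam_result(rownames(diffs), as.numeric(d), m, s, s0, fdrinfo, config,
              ncol(signs), exhaustive = (n <= 30 && 2^n <= config$n_permutations))
}

#' Unpaired two-class SAM with label-permutation FDR
#'
#' Two-class unpaired SAM: `d = (mean2 - mean1) / (s + s0)` with the Tusher
#' pooled standard error
#' `s = sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))`, a null from
#' permuting group labels (exhaustive over all choose(n, n1) assignments
#' when feasible, else a seeded sample), and the same FDR/q-value machinery
#' as the paired analysis.
#'
#' @param expr1,expr2 numeric matrices genes x samples for the two groups
#'   (same genes, same row order).
#' @param config a [sam_config()].
#' @return as [sam_permutation_fdr()]; `mean_diff` is mean2 - mean1 and
#'   `fold_change` its signed linear-scale transform.
#' @export
sam_unpaired <- function(expr1, expr2, config = sam_config()) {
  stopifnot(is.matrix(expr1), is.matrix(expr2),
            nrow(expr1) == nrow(expr2), inherits(config, "sam_config"))
  n1 <- ncol(expr1); n2 <- ncol(expr2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  X <- cbind(expr1, expr2)
  n <- n1 + n2
  const <- sqrt(1 / n1 + 1 / n2)
  rs_total <- rowSums(X)
  ss_total <- rowSums(X^2)

  stat_for <- function(g1_ind) {
    S1 <- X %*% g1_ind                       # genes x B sums of group 1
    m1 <- S1 / n1
    m2 <- (rs_total - S1) / n2
    ssw <- pmax(ss_total - n1 * m1^2 - n2 * m2^2, 0)
    s <- const * sqrt(ssw / (n - 2))
    list(m = m2 - m1, s = s)
  }

  obs <- stat_for(matrix(as.numeric(seq_len(n) <= n1), ncol = 1))
  m <- as.numeric(obs$m); s <- as.numeric(obs$s)
  s0 <- if (is.null(config$s0)) choose_s0(m, s, config$s0_percentiles)
        else config$s0
  d <- m / (s + s0)

  n_total <- choose(n, n1)
  exhaustive <- n_total <= config$n_permutations
  if (exhaustive) {
    combos <- utils::combn(n, n1)
  } else {
    set.seed(config$seed)
    combos <- replicate(config$n_permutations, sort(sample.int(n, n1)))
  }
  ind <- matrix(0, nrow = n, ncol = ncol(combos))
  ind[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = n1))] <- 1
  perm <- stat_for(ind)
  d_perm <- perm$m / (perm$s + s0)

  fdrinfo <- .sam_fdr(d, d_perm, config$n_delta, config$fdr_target)
  .sam_result(rownames(expr1), d, m, s, s0, fdrinfo, config, ncol(combos),
              exhaustive)
}
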