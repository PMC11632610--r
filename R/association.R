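#' Per-study linear association between expression change and lean-mass change
#'
#' For every gene, the Pearson correlation between the per-subject expression
#' change (post minus pre, log2) and the percent change in lean mass is
#' computed within one study, with the two-sided p-value from the t
#' transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)`. A single-predictor linear
#' model F test is equivalent to this t test, so the correlation form is used
#' throughout. All subjects of the study enter, including grey-zone subjects.
#'
#' @param delta_expr numeric matrix genes x subjects of expression changes.
#' @param delta_llm numeric vector of percent lean-mass changes, aligned to
#'   the columns of `delta_expr`.
#' @param study_id study label stamped on the output rows.
#' @return data.frame `gene_id, study_id, r, p, n`. Genes whose expression
#'   change has zero variance get `NA` for `r` and `p` (flagged, excluded
#'   downstream).
#' @export
per_study_association <- function(delta_expr, delta_llm, study_id = "study") {
  stopifnot(is.matrix(delta_expr), ncol(delta_expr) == length(delta_llm))
  n <- length(delta_llm)
  if (n < 3) stop("need at least 3 subjects per study")
  if (stats::sd(delta_llm) == 0) stop("delta_llm has zero variance")
  x <- delta_llm - mean(delta_llm)
  xc <- sqrt(sum(x^2))
  ec <- delta_expr - rowMeans(delta_expr)
  ssg <- sqrt(rowSums(ec^2))
  r <- as.vector(ec %*% x) / (ssg * xc)
  r[ssg == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  data.frame(gene_id = rownames(delta_expr), study_id = study_id,
             r = r, p = p, n = n, stringsAsFactors = FALSE)
}

#' Stouffer combination of per-study p-values
#'
#' Direction-aware Stouffer pooling: each two-sided p is converted to
#' `z_i = qnorm(1 - p_i/2) * sign_i`, summed as `Z = sum(z_i)/sqrt(k)`, and
#' returned as the two-sided `p = 2 * (1 - pnorm(|Z|))`. With
#' `signed = FALSE` the classical unsigned pooling (one-sided z from the raw
#' p, no direction) is used instead.
#'
#' @param p numeric vector of p-values in (0, 1]; zeros are clipped to the
#'   smallest representable double with a warning.
#' @param signs numeric vector of correlation signs (+1/-1), same length.
#' @param signed use direction-aware pooling (default).
#' @return pooled two-sided p-value (scalar).
#' @export
stouffer_pool <- function(p, signs = rep(1, length(p)), signed = TRUE) {
  stopifnot(length(p) == length(signs), length(p) >= 1)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clipped to machine minimum")
    p[p == 0] <- .Machine$double.xmin
  }
  if (signed) {
    z <- stats::qnorm(1 - p / 2) * sign(signs)
    Z <- sum(z) / sqrt(length(z))
    2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  } else {
    z <- stats::qnorm(1 - p)
    Z <- sum(z) / sqrt(length(z))
    stats::pnorm(Z, lower.tail = FALSE)
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as the pipeline's
#' single FDR entry point.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values, same order as the input.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Pool per-study associations and apply the published filters
#'
#' Combines per-study correlation rows into one row per gene: the Stouffer
#' pooled p over the `n_pool` largest studies (by subject count, ties broken
#' by study id order), the median r over all studies, and the count of
#' studies sharing the majority direction. Genes missing a finite r in any
#' study are excluded. The three filters are then applied:
#' (i) median |r| >= `r_min`, (ii) consistent direction in at least
#' `consistency_min` studies, (iii) BH FDR < `fdr_max`, where the FDR is
#' computed only over genes passing (i) and (ii), on their pooled p.
#'
#' @param assoc data.frame of per-study rows as returned by
#'   [per_study_association()] (stacked over studies).
#' @param n_pool number of largest studies whose p-values are pooled.
#' @param r_min minimum median absolute correlation (filter i).
#' @param consistency_min minimum number of same-direction studies (filter ii).
#' @param fdr_max FDR bound (filter iii).
#' @param signed direction-aware Stouffer pooling (see [stouffer_pool()]).
#' @return data.frame `gene_id, pooled_p, median_r, n_consistent, fdr,
#'   pass_median_r, pass_direction, passed`, one row per complete gene.
#'   Attribute `"pooled_studies"` names the studies pooled; attribute
#'   `"excluded"` lists genes dropped for missing studies or undefined r.
#' @export
apply_association_filters <- function(assoc, n_pool = 3, r_min = 0.2,
                                      consistency_min = 4, fdr_max = 0.10,
                                      signed = TRUE) {
  stopifnot(all(c("gene_id", "study_id", "r", "p", "n") %in% names(assoc)))
  studies <- unique(assoc[, c("study_id", "n")])
  studies <- studies[order(-studies$n, studies$study_id), ]
  n_studies <- nrow(studies)
  pool_ids <- studies$study_id[seq_len(min(n_pool, n_studies))]

  ok <- is.finite(assoc$r)
  complete <- names(which(table(assoc$gene_id[ok]) == n_studies))
  excluded <- setdiff(unique(assoc$gene_id), complete)
  a <- assoc[ok & assoc$gene_id %in% complete, ]
  a <- a[order(a$gene_id, a$study_id), ]

  by_gene <- split(a, a$gene_id)
  rows <- lapply(by_gene, function(g) {
    in_pool <- g$study_id %in% pool_ids
    pooled <- stouffer_pool(g$p[in_pool], sign(g$r[in_pool]), signed = signed)
    nsig <- max(sum(g$r > 0), sum(g$r < 0))
    data.frame(gene_id = g$gene_id[1], pooled_p = pooled,
               median_r = stats::median(g$r), n_consistent = nsig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pass_median_r <- abs(out$median_r) >= r_min
  out$pass_direction <- out$n_consistent >= consistency_min
  out$fdr <- NA_real_
  cand <- out$pass_median_r & out$pass_direction
  out$fdr[cand] <- benjamini_hochberg(out$pooled_p[cand])
  out$passed <- cand & !is.na(out$fdr) & out$fdr < fdr_max
  attr(out, "pooled_studies") <- pool_ids
  attr(out, "excluded") <- excluded
  out
}
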