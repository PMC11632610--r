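#' Classify subjects into lean-mass response groups
#'
#' Subjects are stratified against the technical-variation band of the
#' body-composition instrument (DXA leg lean mass or MRI thigh muscle
#' volume). A percent change at or above `upper` marks a Lean-Mass Responder
#' (`"LMR"`), a change below `lower` marks No Measurable Lean-Mass Response
#' (`"NMLMR"`), and changes inside the precision-error band fall in a grey
#' zone (`"GREY"`): those subjects are excluded from the two DE groups but
#' retained for the linear modelling of expression change against lean-mass
#' change.
#'
#' @param dllm_pct numeric vector of percent change in leg lean mass (or
#'   muscle volume), pre to post.
#' @param lower lower bound of the precision-error band (percent); changes
#'   below it are classed `NMLMR`. Default 2.0.
#' @param upper responder threshold (percent); changes at or above it are
#'   classed `LMR`. Default 2.5.
#' @return character vector in `{"LMR","NMLMR","GREY"}` of the same length.
#' @examples
#' classify_response(c(3.0, -1.0, 2.2))
#' @export
classify_response <- function(dllm_pct, lower = 2.0, upper = 2.5) {
  if (!is.numeric(dllm_pct)) stop("dllm_pct must be numeric")
  if (any(!is.finite(dllm_pct))) stop("dllm_pct contains non-finite values")
  if (!(lower < upper)) stop("thresholds must satisfy lower < upper")
  ifelse(dllm_pct >= upper, "LMR", ifelse(dllm_pct < lower, "NMLMR", "GREY"))
}

#' Per-class summary of a phenotype table
#'
#' Counts, percent shares, mean, SD and range of `dllm_pct` per response
#' class, in the form the cohort descriptives are reported (e.g. 88 of 144
#' subjects = 61% responders).
#'
#' @param pheno data.frame with columns `dllm_pct` and (optionally)
#'   `response_class`; if the class column is absent it is derived with
#'   [classify_response()] at default thresholds.
#' @param lower,upper thresholds passed to [classify_response()] when the
#'   class column must be derived.
#' @return data.frame with one row per class (`LMR`, `NMLMR`, `GREY`):
#'   `n`, `pct` (share of all subjects, percent), `mean`, `sd`, `min`, `max`.
#' @export
group_summary <- function(pheno, lower = 2.0, upper = 2.5) {
  stopifnot(is.data.frame(pheno), nrow(pheno) > 0, "dllm_pct" %in% names(pheno))
  cls <- if ("response_class" %in% names(pheno)) pheno$response_class else
    classify_response(pheno$dllm_pct, lower, upper)
  total <- nrow(pheno)
  out <- lapply(c("LMR", "NMLMR", "GREY"), function(g) {
    x <- pheno$dllm_pct[cls == g]
    data.frame(
      response_class = g, n = length(x), pct = 100 * length(x) / total,
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else NA_real_,
      min = if (length(x)) min(x) else NA_real_,
      max = if (length(x)) max(x) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Flag detected genes by SD-based filtering above background
#'
#' Genes are flagged as detected when their median log2 signal exceeds the
#' estimated background mean by `k` background standard deviations, with a
#' stricter multiplier for protein-coding genes (`k_pc`, default 2) than for
#' non-coding genes (`k_nc`, default 1). Without raw array background probes,
#' background is estimated from the matrix itself: per-gene medians are split
#' into a low and a high component by a deterministic 2-means partition
#' (centres initialised at the 10th and 90th percentiles) and the background
#' moments are the mean/SD of the low component. Both moments can be
#' overridden.
#'
#' @param expr numeric matrix, genes x samples, log2 scale, rownames = gene ids.
#' @param catalog data.frame with `gene_id` and `biotype` (one of
#'   `protein_coding`, `lncRNA`, `miscRNA`, `pseudogene`).
#' @param k_pc SD multiplier for protein-coding genes.
#' @param k_nc SD multiplier for non-coding genes.
#' @param bg_mean,bg_sd optional background moments overriding the
#'   lowest-quartile estimate.
#' @return `catalog` with a logical `detected` column added (genes absent
#'   from the matrix get `NA`).
#' @export
detect_expressed <- function(expr, catalog, k_pc = 2, k_nc = 1,
                             bg_mean = NULL, bg_sd = NULL) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            all(c("gene_id", "biotype") %in% names(catalog)))
  med <- apply(expr, 1, stats::median)
  if (is.null(bg_mean) || is.null(bg_sd)) {
    if (stats::sd(med) == 0) stop("background undefined: constant matrix")
    cen <- unname(stats::quantile(med, c(0.1, 0.9)))
    bg <- if (cen[1] < cen[2]) {
      km <- stats::kmeans(med, centers = cen)
      med[km$cluster == which.min(km$centers)]
    } else med[med <= stats::quantile(med, 0.25)]
    if (is.null(bg_mean)) bg_mean <- mean(bg)
    if (is.null(bg_sd)) bg_sd <- stats::sd(bg)
    if (!is.finite(bg_sd) || bg_sd == 0) stop("background SD is zero")
  }
  k <- ifelse(catalog$biotype == "protein_coding", k_pc, k_nc)
  gene_med <- med[match(catalog$gene_id, rownames(expr))]
  catalog$detected <- gene_med > bg_mean + k * bg_sd
  attr(catalog, "background") <- c(mean = bg_mean, sd = bg_sd)
  catalog
}

#' Biotype composition of a gene catalog
#'
#' Counts and percent shares per RNA class, optionally restricted to
#' detected genes.
#'
#' @param catalog data.frame with `biotype` (and `detected` when
#'   `detected_only = TRUE`).
#' @param detected_only restrict to genes flagged detected.
#' @return data.frame with `biotype`, `n`, `pct`.
#' @export
biotype_shares <- function(catalog, detected_only = FALSE) {
  if (detected_only) catalog <- catalog[which(catalog$detected), , drop = FALSE]
  lev <- c("protein_coding", "lncRNA", "miscRNA", "pseudogene")
  n <- vapply(lev, function(b) sum(catalog$biotype == b), integer(1))
  data.frame(biotype = lev, n = as.integer(n), pct = 100 * n / sum(n),
             stringsAsFactors = FALSE)
}
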