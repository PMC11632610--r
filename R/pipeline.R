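#' Run the full ncRNA signature discovery pipeline on a paired cohort
#'
#' Chains the discovery stages on a multi-study paired cohort: response
#' classification (already stamped on the phenotype table), paired SAM
#' differential expression of ncRNA genes within the responder (LMR) and
#' non-responder (NMLMR) groups, the cross-group heuristic fold-change
#' filter, per-study linear association of expression change with lean-mass
#' change pooled by the signed Stouffer method over the largest studies with
#' the three published filters, and signature assembly by union.
#'
#' @param cohort list from [generate_cohort()] (or equivalent structures
#'   read from disk: `pheno`, `expr_pre`, `expr_post`, `catalog`).
#' @param sam sam analysis settings, a [sam_config()].
#' @param ratio_min between-group fold-change ratio for the heuristic filter.
#' @param n_pool,r_min,consistency_min,fdr_max association-filter settings
#'   (see [apply_association_filters()]).
#' @return list with `de_lmr`, `de_nmlmr`, `heuristics`, `assoc`
#'   (per-study rows), `pooled`, and `signature` (a `signature_set`).
#' @export
run_signature_pipeline <- function(cohort, sam = sam_config(),
                                   ratio_min = 1.2, n_pool = 3, r_min = 0.2,
                                   consistency_min = 4, fdr_max = 0.10) {
  pheno <- cohort$pheno
  catalog <- cohort$catalog
  nc_genes <- catalog$gene_id[catalog$biotype != "protein_coding"]
  diffs <- (cohort$expr_post - cohort$expr_pre)[nc_genes, , drop = FALSE]

  lmr_sub <- pheno$subject_id[pheno$response_class == "LMR"]
  nml_sub <- pheno$subject_id[pheno$response_class == "NMLMR"]
  de_lmr <- sam_permutation_fdr(diffs[, lmr_sub, drop = FALSE], sam)
  de_nmlmr <- sam_permutation_fdr(diffs[, nml_sub, drop = FALSE], sam)

  heur <- heuristic_filter(de_lmr, de_nmlmr, ratio_min = ratio_min)
  lmr_unique <- heur$gene_id[heur$kept & heur$group == "LMR"]
  nmlmr_unique <- heur$gene_id[heur$kept & heur$group == "NMLMR"]

  assoc <- do.call(rbind, lapply(unique(pheno$study_id), function(st) {
    sub <- pheno$subject_id[pheno$study_id == st]
    per_study_association(diffs[, sub, drop = FALSE],
                          pheno$dllm_pct[match(sub, pheno$subject_id)],
                          study_id = st)
  }))
  pooled <- apply_association_filters(assoc, n_pool = n_pool, r_min = r_min,
                                      consistency_min = consistency_min,
                                      fdr_max = fdr_max)
  linear_set <- pooled$gene_id[pooled$passed]

  signature <- assemble_signature(lmr_unique, nmlmr_unique, linear_set)
  list(de_lmr = de_lmr, de_nmlmr = de_nmlmr, heuristics = heur,
       assoc = assoc, pooled = pooled, signature = signature)
}

#' Sensitivity and false-discovery proportion of a recovered signature
#'
#' @param signature a `signature_set` (or character vector of gene ids).
#' @param truth ground-truth list from [generate_cohort()].
#' @return named vector `sensitivity`, `fdp`, `n_called`, `n_planted`.
#' @export
signature_recovery <- function(signature, truth) {
  called <- if (inherits(signature, "signature_set")) signature$final
            else as.character(signature)
  planted <- unique(c(truth$planted_lmr_genes, truth$planted_nmlmr_genes,
                      truth$planted_linear_genes))
  tp <- length(intersect(called, planted))
  c(sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
    fdp = if (length(called)) (length(called) - tp) / length(called) else 0,
    n_called = length(called), n_planted = length(planted))
}
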