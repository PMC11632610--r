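#' Cross-group heuristic fold-change filter
#'
#' Prioritises differentially expressed ncRNA genes whose regulation pattern
#' is distinct between the responder (LMR) and non-responder (NMLMR) groups.
#' Every gene significant in at least one group is assessed on the fold
#' changes observed in *both* groups: it is kept when the signed fold
#' changes point in opposite directions, or when the ratio of the larger to
#' the smaller fold-change magnitude is at least `ratio_min` (for
#' same-direction pairs this equals requiring
#' |delta log2FC| >= log2(ratio_min)). A gene whose counterpart fold change
#' is unavailable is kept as `unique_to_group`. With
#' `unique_rule = "significance"` genes significant in exactly one group
#' are instead kept outright and the opposite/ratio rule only arbitrates
#' genes significant in both.
#'
#' @param de_lmr,de_nmlmr DE result tables (as returned by
#'   [sam_permutation_fdr()]) for the two response groups; must share the
#'   signed fold-change convention (|FC| >= 1).
#' @param ratio_min minimum between-group fold-change ratio.
#' @param unique_rule `"fc_distinct"` (default: the fold-change heuristic
#'   applies to all significant genes) or `"significance"`.
#' @return data.frame `gene_id, fc_lmr, fc_nmlmr, sig_lmr, sig_nmlmr,
#'   opposite_direction, fc_ratio, kept, reason, group` for every gene
#'   significant in at least one group. `reason` is one of `unique_to_group`,
#'   `opposite`, `ratio`, `dropped`; `group` attributes the kept gene to
#'   `LMR` or `NMLMR` (genes significant in both: the group with the larger
#'   |FC|).
#' @export
heuristic_filter <- function(de_lmr, de_nmlmr, ratio_min = 1.2,
                             unique_rule = c("fc_distinct", "significance")) {
  unique_rule <- match.arg(unique_rule)
  need <- c("gene_id", "fold_change", "called")
  stopifnot(all(need %in% names(de_lmr)), all(need %in% names(de_nmlmr)))
  if (any(abs(de_lmr$fold_change) < 1) || any(abs(de_nmlmr$fold_change) < 1))
    stop("fold changes must follow the signed convention (|FC| >= 1)")
  genes <- union(de_lmr$gene_id[de_lmr$called], de_nmlmr$gene_id[de_nmlmr$called])
  if (!length(genes)) {
    return(data.frame(gene_id = character(), fc_lmr = numeric(),
                      fc_nmlmr = numeric(), sig_lmr = logical(),
                      sig_nmlmr = logical(), opposite_direction = logical(),
                      fc_ratio = numeric(), kept = logical(),
                      reason = character(), group = character(),
                      stringsAsFactors = FALSE))
  }
  i1 <- match(genes, de_lmr$gene_id)
  i2 <- match(genes, de_nmlmr$gene_id)
  fc1 <- de_lmr$fold_change[i1]
  fc2 <- de_nmlmr$fold_change[i2]
  sig1 <- !is.na(i1) & de_lmr$called[i1]
  sig2 <- !is.na(i2) & de_nmlmr$called[i2]
  both <- sig1 & sig2
  have_both_fc <- !is.na(fc1) & !is.na(fc2)
  # genes the opposite/ratio heuristic arbitrates; the rest fall back to
  # unique_to_group (counterpart FC missing, or one-group-significant under
  # the "significance" rule)
  assess <- if (unique_rule == "fc_distinct") have_both_fc
            else both & have_both_fc
  opp <- assess & sign(fc1) != sign(fc2)
  ratio <- ifelse(have_both_fc,
                  pmax(abs(fc1), abs(fc2)) / pmin(abs(fc1), abs(fc2)),
                  NA_real_)
  reason <- rep("dropped", length(genes))
  reason[assess & !opp & ratio >= ratio_min] <- "ratio"
  reason[opp] <- "opposite"
  reason[!assess] <- "unique_to_group"
  kept <- reason != "dropped"
  group <- ifelse(both, ifelse(abs(fc1) >= abs(fc2), "LMR", "NMLMR"),
                  ifelse(sig1, "LMR", "NMLMR"))
  data.frame(gene_id = genes, fc_lmr = fc1, fc_nmlmr = fc2,
             sig_lmr = sig1, sig_nmlmr = sig2, opposite_direction = opp,
             fc_ratio = ratio, kept = kept, reason = reason, group = group,
             stringsAsFactors = FALSE)
}

#' Assemble the hypertrophy signature by union of candidate sets
#'
#' Unions the uniquely regulated responder genes, the uniquely regulated
#' non-responder genes and the linear-association genes into the final
#' signature, and reports every pairwise and triple intersection so the
#' cardinality can be audited by inclusion-exclusion:
#' `|final| = sum |sets| - sum |pairwise| + |triple|`.
#'
#' @param lmr_unique,nmlmr_unique,linear_set character vectors of gene ids.
#' @return list of class `signature_set` with elements `lmr_unique`,
#'   `nmlmr_unique`, `linear_set`, `final`, and `overlap_table` (named
#'   intersection counts including the triple).
#' @export
assemble_signature <- function(lmr_unique, nmlmr_unique, linear_set) {
  lmr_unique <- unique(as.character(lmr_unique))
  nmlmr_unique <- unique(as.character(nmlmr_unique))
  linear_set <- unique(as.character(linear_set))
  final <- union(union(lmr_unique, nmlmr_unique), linear_set)
  ov <- c(
    lmr = length(lmr_unique), nmlmr = length(nmlmr_unique),
    linear = length(linear_set),
    lmr_nmlmr = length(intersect(lmr_unique, nmlmr_unique)),
    lmr_linear = length(intersect(lmr_unique, linear_set)),
    nmlmr_linear = length(intersect(nmlmr_unique, linear_set)),
    triple = length(intersect(intersect(lmr_unique, nmlmr_unique), linear_set))
  )
  stopifnot(length(final) ==
              ov["lmr"] + ov["nmlmr"] + ov["linear"] -
              ov["lmr_nmlmr"] - ov["lmr_linear"] - ov["nmlmr_linear"] +
              ov["triple"])
  structure(list(lmr_unique = lmr_unique, nmlmr_unique = nmlmr_unique,
                 linear_set = linear_set, final = final, overlap_table = ov),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("Hypertrophy ncRNA signature\n")
  cat(sprintf("  LMR-unique: %d  NMLMR-unique: %d  linear: %d  final: %d\n",
              length(x$lmr_unique), length(x$nmlmr_unique),
              length(x$linear_set), length(x$final)))
  invisible(x)
}

#' Overlap of a signature with reference gene sets
#'
#' Per-reference intersection counts and the fraction of the signature
#' covered; for up to three references the Venn-style region counts over
#' the signature are reported as well.
#'
#' @param signature character vector of gene ids (non-empty).
#' @param reference_sets named list of character vectors.
#' @return list with `per_reference` (data.frame `reference, n_overlap,
#'   fraction`) and `regions` (named counts of signature genes per
#'   membership pattern, `NULL` when more than 3 references).
#' @export
overlap_report <- function(signature, reference_sets) {
  stopifnot(length(signature) > 0, is.list(reference_sets),
            !is.null(names(reference_sets)))
  signature <- unique(as.character(signature))
  per <- do.call(rbind, lapply(names(reference_sets), function(nm) {
    k <- length(intersect(signature, reference_sets[[nm]]))
    data.frame(reference = nm, n_overlap = k,
               fraction = k / length(signature), stringsAsFactors = FALSE)
  }))
  regions <- NULL
  if (length(reference_sets) <= 3) {
    member <- vapply(reference_sets, function(s) signature %in% s,
                     logical(length(signature)))
    member <- matrix(member, nrow = length(signature))
    pattern <- apply(member, 1, function(z) paste(as.integer(z), collapse = ""))
    all_pat <- apply(expand.grid(rep(list(0:1), length(reference_sets))), 1,
                     paste, collapse = "")
    regions <- vapply(all_pat, function(pt) sum(pattern == pt), integer(1))
  }
  list(per_reference = per, regions = regions)
}
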