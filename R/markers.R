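#' Cell-type marker panels for bulk skeletal muscle
#'
#' The marker genes used to index myonuclear and mononuclear cell types in
#' bulk muscle tissue: type I fibres (MYH7, TNNT1), type II fibres (MYH1,
#' MYH2, ATP2A1, TNNT3), satellite cells (PAX7, MYF5), endothelial cells
#' (ENG, TIE1, PECAM1, APLNR), pericytes (RGS5, HIGD1B), macrophages (F13A1,
#' SPP1), T cells (CD3D, IL7R) and B cells (MS4A1, CD79A) - 8 cell types,
#' 20 genes. The same panels ship as a GMT file under `extdata/`.
#'
#' @return named list of character vectors (cell type -> marker genes).
#' @export
marker_panels <- function() {
  list(
    type_I_fibre   = c("MYH7", "TNNT1"),
    type_II_fibre  = c("MYH1", "MYH2", "ATP2A1", "TNNT3"),
    satellite_cell = c("PAX7", "MYF5"),
    endothelial    = c("ENG", "TIE1", "PECAM1", "APLNR"),
    pericyte       = c("RGS5", "HIGD1B"),
    macrophage     = c("F13A1", "SPP1"),
    T_cell         = c("CD3D", "IL7R"),
    B_cell         = c("MS4A1", "CD79A")
  )
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT requires the fgsea package")
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (second GMT column).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Correlate query genes with cell-type marker genes
#'
#' Pearson correlation of each query gene against each marker gene across
#' the samples of a single-timepoint cohort, with two-sided p-values from
#' the t transform and BH FDR across all pairs tested in the call.
#' Zero-variance queries or markers are skipped (recorded in the
#' `"skipped"` attribute). Correlations operate directly on the log2 signal.
#'
#' @param expr numeric matrix genes x samples (log2), >= 10 samples.
#' @param queries character vector of query gene ids present in `expr`.
#' @param panels named list of marker genes per cell type (defaults to
#'   [marker_panels()]); markers absent from the matrix are ignored.
#' @return data.frame `query_id, marker_gene, cell_type, r, p, fdr`.
#' @export
marker_correlation <- function(expr, queries, panels = marker_panels()) {
  stopifnot(is.matrix(expr), ncol(expr) >= 10)
  queries <- intersect(queries, rownames(expr))
  if (!length(queries)) stop("no query genes present in the matrix")
  marker_df <- data.frame(
    marker_gene = unlist(panels, use.names = FALSE),
    cell_type = rep(names(panels), lengths(panels)),
    stringsAsFactors = FALSE)
  marker_df <- marker_df[marker_df$marker_gene %in% rownames(expr), ]
  if (!nrow(marker_df)) stop("no marker genes present in the matrix")
  n <- ncol(expr)
  qv <- apply(expr[queries, , drop = FALSE], 1, stats::var)
  mv <- apply(expr[marker_df$marker_gene, , drop = FALSE], 1, stats::var)
  skipped <- c(queries[qv == 0], marker_df$marker_gene[mv == 0])
  queries <- queries[qv > 0]
  marker_df <- marker_df[mv > 0, ]
  cm <- stats::cor(t(expr[queries, , drop = FALSE]),
                   t(expr[marker_df$marker_gene, , drop = FALSE]))
  out <- data.frame(
    query_id = rep(queries, times = nrow(marker_df)),
    marker_gene = rep(marker_df$marker_gene, each = length(queries)),
    cell_type = rep(marker_df$cell_type, each = length(queries)),
    r = as.vector(cm), stringsAsFactors = FALSE)
  tt <- abs(out$r) * sqrt(n - 2) / sqrt(pmax(1 - out$r^2, .Machine$double.eps))
  out$p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  out$fdr <- benjamini_hochberg(out$p)
  attr(out, "skipped") <- skipped
  out
}

#' Cell-type profile of a co-expression module
#'
#' Summarises a module by a single signal - the mean of its mean-centred,
#' unit-scaled member rows (default; robust for modules as small as 3
#' genes), or the first principal-component score with
#' `summary = "eigen"` - then correlates that signal against every marker
#' gene and aggregates mean r per cell type.
#'
#' @param expr numeric matrix genes x samples (log2).
#' @param module character vector of member gene ids (>= 3, all present).
#' @param panels named list of marker genes per cell type.
#' @param summary `"scaled_average"` (default) or `"eigen"`.
#' @return list with `profile` (data.frame `cell_type, mean_r, n_markers`,
#'   sorted by decreasing mean r), `per_marker` (data.frame
#'   `marker_gene, cell_type, r`) and `signal` (the module summary vector).
#' @export
module_marker_profile <- function(expr, module, panels = marker_panels(),
                                  summary = c("scaled_average", "eigen")) {
  summary <- match.arg(summary)
  if (length(module) < 3) stop("module must have at least 3 genes")
  missing_m <- setdiff(module, rownames(expr))
  if (length(missing_m))
    stop("module genes absent from matrix: ", paste(missing_m, collapse = ", "))
  X <- expr[module, , drop = FALSE]
  Xs <- t(scale(t(X)))
  Xs[!is.finite(Xs)] <- 0
  signal <- if (summary == "scaled_average") colMeans(Xs) else
    stats::prcomp(t(Xs), center = FALSE, scale. = FALSE)$x[, 1]
  marker_df <- data.frame(
    marker_gene = unlist(panels, use.names = FALSE),
    cell_type = rep(names(panels), lengths(panels)),
    stringsAsFactors = FALSE)
  marker_df <- marker_df[marker_df$marker_gene %in% rownames(expr), ]
  marker_df$r <- apply(expr[marker_df$marker_gene, , drop = FALSE], 1,
                       function(m) suppressWarnings(stats::cor(signal, m)))
  marker_df$r[is.na(marker_df$r)] <- 0
  prof <- do.call(rbind, lapply(split(marker_df, marker_df$cell_type),
    function(g) data.frame(cell_type = g$cell_type[1], mean_r = mean(g$r),
                           n_markers = nrow(g), stringsAsFactors = FALSE)))
  prof <- prof[order(-prof$mean_r), ]
  rownames(prof) <- NULL
  list(profile = prof, per_marker = marker_df, signal = signal)
}
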