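#' Write / read a genes-x-samples expression matrix as TSV
#'
#' Genes as rows (first column `gene_id`), samples as columns.
#'
#' @param mat numeric matrix with rownames.
#' @param path file path.
#' @export
write_expression_tsv <- function(mat, path) {
  dt <- data.table::as.data.table(mat, keep.rownames = "gene_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' Write / read a data frame as TSV
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_table_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write a full simulated cohort to a directory
#'
#' Writes `pheno.tsv`, `expr_pre.tsv`, `expr_post.tsv`, `catalog.tsv` and
#' `truth.json` (ground truth as JSON).
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table_tsv(cohort$pheno, file.path(dir, "pheno.tsv"))
  write_expression_tsv(cohort$expr_pre, file.path(dir, "expr_pre.tsv"))
  write_expression_tsv(cohort$expr_post, file.path(dir, "expr_post.tsv"))
  write_table_tsv(cohort$catalog, file.path(dir, "catalog.tsv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write a simulator configuration (JSON or YAML by extension)
#'
#' @param config a [sim_config()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$n_genes_by_biotype <- as.list(x$n_genes_by_biotype)  # keep names on disk
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML output requires the yaml package")
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML input requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  x$n_genes_by_biotype <- unlist(x$n_genes_by_biotype)
  do.call(sim_config, x)
}
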