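#' Configuration for the multi-study cohort simulator
#'
#' Defaults reproduce the statistical shape of the five resistance-training
#' cohorts the pipeline targets: study sizes 32/33/47/20/12 (144 subjects,
#' 288 pre/post profiles), a 61% responder fraction with percent lean-mass
#' change drawn from a two-component Gaussian mixture (responders
#' 6.6 +/- 3.9%, non-responders -0.6 +/- 1.8%; no truncation, so grey-zone
#' subjects arise naturally), and a ~2000-gene catalog whose biotype
#' proportions mirror the detected-gene composition of bulk muscle arrays
#' (protein-coding 1159, lncRNA 627, miscRNA 104, pseudogene 110). Planted
#' effects: responder-specific and non-responder-specific shifts of
#' `planted_log2fc` log2 units, and genes whose expression change is
#' linearly proportional to lean-mass change with slope `linear_slope`
#' (log2 units per percent). All randomness flows from `seed` through a
#' fixed splitting scheme (catalog: seed; paired cohort: seed + 1; network
#' cohort: seed + 2).
#'
#' @param n_studies number of studies.
#' @param study_sizes subjects per study (length `n_studies`).
#' @param responder_fraction mixture weight of the responder component.
#' @param lmr_dllm_mean,lmr_dllm_sd responder %dLLM component (percent).
#' @param nmlmr_dllm_mean,nmlmr_dllm_sd non-responder component (percent).
#' @param n_genes_by_biotype named counts for `protein_coding`, `lncRNA`,
#'   `miscRNA`, `pseudogene`.
#' @param n_planted_lmr,n_planted_nmlmr,n_planted_linear planted ncRNA counts.
#' @param planted_log2fc group-specific shift (log2 units).
#' @param linear_slope slope of the lean-mass-linear genes (log2 per %dLLM).
#' @param noise_sd per-measurement residual SD (log2 units).
#' @param baseline_corr within-subject pre/post baseline correlation.
#' @param n_celltypes number of latent cell types (the 8 printed panels).
#' @param markers_per_celltype synthetic latent-driven ncRNA query genes per
#'   cell type (in addition to the printed protein-coding markers).
#' @param n_modules,module_size,module_rho block-correlated module layout of
#'   the network cohort.
#' @param network_n samples in the single-timepoint network cohort.
#' @param seed integer master seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 5,
                       study_sizes = c(32, 33, 47, 20, 12),
                       responder_fraction = 0.61,
                       lmr_dllm_mean = 6.6, lmr_dllm_sd = 3.9,
                       nmlmr_dllm_mean = -0.6, nmlmr_dllm_sd = 1.8,
                       n_genes_by_biotype = c(protein_coding = 1159,
                                              lncRNA = 627, miscRNA = 104,
                                              pseudogene = 110),
                       n_planted_lmr = 20, n_planted_nmlmr = 8,
                       n_planted_linear = 10,
                       planted_log2fc = 1.0, linear_slope = 0.1,
                       noise_sd = 0.7, baseline_corr = 0.5,
                       n_celltypes = 8, markers_per_celltype = 2,
                       n_modules = 5, module_size = 30, module_rho = 0.7,
                       network_n = 437, seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              study_sizes = as.integer(study_sizes),
              responder_fraction = responder_fraction,
              lmr_dllm_mean = lmr_dllm_mean, lmr_dllm_sd = lmr_dllm_sd,
              nmlmr_dllm_mean = nmlmr_dllm_mean, nmlmr_dllm_sd = nmlmr_dllm_sd,
              n_genes_by_biotype = n_genes_by_biotype,
              n_planted_lmr = as.integer(n_planted_lmr),
              n_planted_nmlmr = as.integer(n_planted_nmlmr),
              n_planted_linear = as.integer(n_planted_linear),
              planted_log2fc = planted_log2fc, linear_slope = linear_slope,
              noise_sd = noise_sd, baseline_corr = baseline_corr,
              n_celltypes = as.integer(n_celltypes),
              markers_per_celltype = as.integer(markers_per_celltype),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_rho = module_rho, network_n = as.integer(network_n),
              seed = as.integer(seed))
  if (length(cfg$study_sizes) != cfg$n_studies)
    stop("study_sizes must have length n_studies")
  if (any(cfg$study_sizes <= 0) || any(cfg$n_genes_by_biotype <= 0))
    stop("all counts must be positive")
  if (cfg$responder_fraction <= 0 || cfg$responder_fraction >= 1)
    stop("responder_fraction must lie in (0, 1)")
  if (cfg$module_rho < 0 || cfg$module_rho >= 1)
    stop("module_rho must lie in [0, 1)")
  if (cfg$baseline_corr < 0 || cfg$baseline_corr >= 1)
    stop("baseline_corr must lie in [0, 1)")
  n_nc <- sum(cfg$n_genes_by_biotype[c("lncRNA", "miscRNA", "pseudogene")])
  if (cfg$n_planted_lmr + cfg$n_planted_nmlmr + cfg$n_planted_linear > n_nc)
    stop("planted counts exceed the ncRNA catalog size")
  structure(cfg, class = "sim_config")
}

# gene catalog + planted/annotation choices; deterministic given config$seed
.build_catalog <- function(config) {
  set.seed(config$seed)
  nb <- config$n_genes_by_biotype
  ids <- c(sprintf("PC%04d", seq_len(nb[["protein_coding"]])),
           sprintf("LNC%04d", seq_len(nb[["lncRNA"]])),
           sprintf("MISC%04d", seq_len(nb[["miscRNA"]])),
           sprintf("PSG%04d", seq_len(nb[["pseudogene"]])))
  biotype <- rep(c("protein_coding", "lncRNA", "miscRNA", "pseudogene"),
                 times = nb)
  panels <- marker_panels()[seq_len(min(config$n_celltypes,
                                        length(marker_panels())))]
  markers <- unlist(panels, use.names = FALSE)
  if (length(markers) > nb[["protein_coding"]])
    stop("protein-coding catalog too small for the marker panels")
  ids[seq_along(markers)] <- markers   # printed markers are protein-coding
  catalog <- data.frame(gene_id = ids, biotype = biotype,
                        stringsAsFactors = FALSE)
  nc_ids <- catalog$gene_id[catalog$biotype != "protein_coding"]
  # latent-driven ncRNA query genes, then planted sets, all disjoint
  n_query <- config$markers_per_celltype * length(panels)
  pick <- sample(nc_ids, n_query + config$n_planted_lmr +
                   config$n_planted_nmlmr + config$n_planted_linear)
  query_genes <- if (n_query) pick[seq_len(n_query)] else character(0)
  rest <- pick[-seq_len(n_query)]
  planted_lmr <- rest[seq_len(config$n_planted_lmr)]
  rest <- rest[-seq_len(config$n_planted_lmr)]
  planted_nmlmr <- if (config$n_planted_nmlmr)
    rest[seq_len(config$n_planted_nmlmr)] else character(0)
  rest <- if (config$n_planted_nmlmr) rest[-seq_len(config$n_planted_nmlmr)]
          else rest
  planted_linear <- if (config$n_planted_linear)
    rest[seq_len(config$n_planted_linear)] else character(0)
  # baseline log2 abundance: expressed mode plus a low-signal background mode
  is_bg <- stats::runif(nrow(catalog)) < 0.15
  mu <- ifelse(is_bg, stats::rnorm(nrow(catalog), 3.2, 0.6),
               stats::rnorm(nrow(catalog), 7.0, 1.5))
  names(mu) <- catalog$gene_id
  celltype_queries <- if (n_query)
    data.frame(gene_id = query_genes,
               cell_type = rep(names(panels),
                               each = config$markers_per_celltype),
               stringsAsFactors = FALSE)
    else data.frame(gene_id = character(), cell_type = character())
  list(catalog = catalog, mu = mu, panels = panels,
       planted_lmr = planted_lmr, planted_nmlmr = planted_nmlmr,
       planted_linear = planted_linear, celltype_queries = celltype_queries)
}

#' Generate a paired multi-study training cohort
#'
#' Draws per-study subjects with percent lean-mass change from the
#' two-component mixture, then paired pre/post log2 expression: a shared
#' per-subject baseline effect (inducing `baseline_corr` between pre and
#' post), independent Gaussian measurement noise on the log2 scale, and the
#' planted effects - responder-specific shifts, non-responder-specific
#' shifts (alternating signs across planted genes), and changes linearly
#' proportional to lean-mass change in all subjects. All other genes are
#' null.
#'
#' @param config a [sim_config()].
#' @return list with `pheno` (subject_id, study_id, instrument,
#'   baseline_llm, dllm_pct, response_class, responder_component),
#'   `expr_pre` / `expr_post` (genes x subjects log2 matrices), `catalog`,
#'   and `truth` (planted gene sets with their signs, recorded before noise).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cat_info <- .build_catalog(config)
  set.seed(config$seed + 1L)

  sizes <- config$study_sizes
  n_sub <- sum(sizes)
  study <- rep(sprintf("study%d", seq_along(sizes)), times = sizes)
  subject <- sprintf("%s_s%02d", study,
                     unlist(lapply(sizes, seq_len), use.names = FALSE))
  instrument <- ifelse(study == "study4", "MRI", "DXA")
  responder <- stats::runif(n_sub) < config$responder_fraction
  dllm <- ifelse(responder,
                 stats::rnorm(n_sub, config$lmr_dllm_mean, config$lmr_dllm_sd),
                 stats::rnorm(n_sub, config$nmlmr_dllm_mean,
                              config$nmlmr_dllm_sd))
  baseline_llm <- ifelse(instrument == "DXA",
                         stats::rnorm(n_sub, 9.5, 1.2),
                         stats::rnorm(n_sub, 1600, 180))
  pheno <- data.frame(subject_id = subject, study_id = study,
                      instrument = instrument, baseline_llm = baseline_llm,
                      dllm_pct = dllm,
                      response_class = classify_response(dllm),
                      responder_component = responder,
                      stringsAsFactors = FALSE)

  catalog <- cat_info$catalog
  G <- nrow(catalog)
  mu <- cat_info$mu
  sd_b <- sqrt(config$baseline_corr) * config$noise_sd
  sd_w <- sqrt(1 - config$baseline_corr) * config$noise_sd
  base <- matrix(mu, nrow = G, ncol = n_sub) +
    matrix(stats::rnorm(G * n_sub, 0, sd_b), G, n_sub)
  pre <- base + matrix(stats::rnorm(G * n_sub, 0, sd_w), G, n_sub)
  post <- base + matrix(stats::rnorm(G * n_sub, 0, sd_w), G, n_sub)

  effect <- matrix(0, G, n_sub)
  sgn <- function(k) rep_len(c(1, -1), k)
  idx_lmr <- match(cat_info$planted_lmr, catalog$gene_id)
  if (length(idx_lmr))
    effect[idx_lmr, responder] <- effect[idx_lmr, responder] +
      sgn(length(idx_lmr)) * config$planted_log2fc
  idx_nml <- match(cat_info$planted_nmlmr, catalog$gene_id)
  if (length(idx_nml))
    effect[idx_nml, !responder] <- effect[idx_nml, !responder] +
      sgn(length(idx_nml)) * config$planted_log2fc
  idx_lin <- match(cat_info$planted_linear, catalog$gene_id)
  if (length(idx_lin))
    effect[idx_lin, ] <- effect[idx_lin, ] +
      outer(sgn(length(idx_lin)) * config$linear_slope, dllm)
  post <- post + effect

  dimnames(pre) <- dimnames(post) <- list(catalog$gene_id, subject)
  truth <- list(planted_lmr_genes = cat_info$planted_lmr,
                planted_nmlmr_genes = cat_info$planted_nmlmr,
                planted_linear_genes = cat_info$planted_linear,
                planted_signs = list(
                  lmr = sgn(length(idx_lmr)),
                  nmlmr = sgn(length(idx_nml)),
                  linear = sgn(length(idx_lin))),
                celltype_queries = cat_info$celltype_queries)
  list(pheno = pheno, expr_pre = pre, expr_post = post,
       catalog = catalog, truth = truth)
}

#' Generate a single-timepoint network cohort
#'
#' A baseline-only expression matrix (default 437 samples) with (a) latent
#' cell-type abundances driving both the printed protein-coding marker genes
#' and a few synthetic ncRNA query genes per cell type, and (b)
#' block-correlated modules: each module's genes share a latent factor so
#' that every within-module gene pair correlates at about `module_rho`. One
#' planted responder ncRNA is swapped into each module so candidate lookup
#' is exercised. All remaining genes are independent noise around their
#' baseline abundance.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (genes x samples log2 matrix), `catalog`, and
#'   `truth` (`module_memberships`, `celltype_loadings`).
#' @export
generate_network_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cat_info <- .build_catalog(config)
  catalog <- cat_info$catalog
  G <- nrow(catalog)
  if (config$n_modules * config$module_size > G)
    stop("module_size x n_modules exceeds the gene count")
  set.seed(config$seed + 2L)
  n <- config$network_n
  mu <- cat_info$mu
  sd_t <- config$noise_sd
  expr <- matrix(mu, G, n) + matrix(stats::rnorm(G * n, 0, sd_t), G, n)
  rownames(expr) <- catalog$gene_id
  colnames(expr) <- sprintf("net_s%03d", seq_len(n))

  # latent cell-type abundances -> markers and ncRNA query genes
  panels <- cat_info$panels
  z <- matrix(stats::rnorm(length(panels) * n), length(panels), n,
              dimnames = list(names(panels), NULL))
  loading <- 1.0
  loadings <- data.frame(gene_id = character(), cell_type = character(),
                         loading = numeric(), stringsAsFactors = FALSE)
  for (ct in names(panels)) {
    genes <- c(panels[[ct]],
               cat_info$celltype_queries$gene_id[
                 cat_info$celltype_queries$cell_type == ct])
    genes <- intersect(genes, rownames(expr))
    expr[genes, ] <- expr[genes, ] +
      matrix(loading * z[ct, ], length(genes), n, byrow = TRUE)
    loadings <- rbind(loadings,
                      data.frame(gene_id = genes, cell_type = ct,
                                 loading = loading, stringsAsFactors = FALSE))
  }

  # block-correlated modules (exclude marker/query/planted-linear genes)
  reserved <- c(loadings$gene_id, cat_info$planted_linear)
  free <- setdiff(catalog$gene_id, reserved)
  memberships <- list()
  if (config$n_modules > 0) {
    pool <- sample(free, config$n_modules * config$module_size)
    planted_pool <- cat_info$planted_lmr
    for (mdx in seq_len(config$n_modules)) {
      mem <- pool[(mdx - 1) * config$module_size + seq_len(config$module_size)]
      if (mdx <= length(planted_pool) && !(planted_pool[mdx] %in% pool))
        mem[1] <- planted_pool[mdx]   # seed one candidate ncRNA per module
      u <- stats::rnorm(n)
      rho <- config$module_rho
      expr[mem, ] <- matrix(mu[mem], length(mem), n) +
        sd_t * (sqrt(rho) * matrix(u, length(mem), n, byrow = TRUE) +
                  sqrt(1 - rho) * matrix(stats::rnorm(length(mem) * n),
                                         length(mem), n))
      memberships[[sprintf("M%02d", mdx)]] <- mem
    }
  }
  truth <- list(module_memberships = memberships,
                celltype_loadings = loadings,
                celltype_queries = cat_info$celltype_queries)
  list(expr = expr, catalog = catalog, truth = truth)
}
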