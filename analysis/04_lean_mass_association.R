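#!/usr/bin/env Rscript
# Per-study Pearson association between ncRNA expression change and percent
# lean-mass change (all subjects, grey zone included), pooled by the signed
# Stouffer method over the three largest studies, then the three published
# filters: median |r| >= 0.2, direction consistency in 4/5 studies, and
# BH FDR < 10% over the survivors.
suppressPackageStartupMessages(library(hypernc))

pheno <- read_table_tsv("results/data/cohort/pheno.tsv")
catalog <- read_table_tsv("results/data/cohort/catalog.tsv")
pre <- read_expression_tsv("results/data/cohort/expr_pre.tsv")
post <- read_expression_tsv("results/data/cohort/expr_post.tsv")

nc <- catalog$gene_id[catalog$biotype != "protein_coding"]
diffs <- (post - pre)[nc, ]
assoc <- do.call(rbind, lapply(unique(pheno$study_id), function(st) {
  subj <- pheno$subject_id[pheno$study_id == st]
  per_study_association(diffs[, subj],
                        pheno$dllm_pct[match(subj, pheno$subject_id)], st)
}))
write_table_tsv(assoc, "results/association_per_study.tsv")

pooled <- apply_association_filters(assoc)
write_table_tsv(pooled, "results/association_pooled.tsv")

hits <- pooled[pooled$passed, ]
cat(sprintf("Pooled over: %s.\n",
            paste(attr(pooled, "pooled_studies"), collapse = ", ")))
cat(sprintf("%d of %d ncRNA genes pass filters i+ii; %d also pass FDR < 10%%.\n",
            sum(pooled$pass_median_r & pooled$pass_direction),
            nrow(pooled), nrow(hits)))
cat(sprintf("Median |r| of the passing genes: %.2f; median FDR: %.0f%%.\n",
            median(abs(hits$median_r)), 100 * median(hits$fdr)))
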