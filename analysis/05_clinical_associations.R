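#!/usr/bin/env Rscript
# Stage 5: clinical validation of the top panel's genes — case/control
# expression tests in every cohort, Spearman correlation with the
# glomerular filtration rate, pathological-stage comparisons, and
# hypergeometric over-representation of the top module against the curated
# gene-set collection.

suppressMessages(library(lnmeta))

cohorts <- lapply(1:4, function(i) {
  read_bulk_cohort("results/data/bulk", sprintf("cohort%d", i),
                   role = if (i <= 2) "train" else "validation")
})
lb <- utils::read.delim("results/leaderboard.tsv")
top_panel <- lb$panel[which.max(lb$mean_validation_cindex)]
sets <- read_gmt("results/data/gene_sets.gmt")
mp_sets <- read_gmt("results/metaprograms.gmt")
parts <- strsplit(top_panel, "x", fixed = TRUE)[[1]]
genes <- intersect(mp_sets[[parts[1]]], sets[[parts[2]]])
genes <- intersect(genes, colnames(cohorts[[1]]$expression))
message(sprintf("top panel %s: %d genes", top_panel, length(genes)))

assoc <- do.call(rbind, lapply(cohorts, case_control_test, genes = genes))
utils::write.table(assoc, "results/associations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
sig_up <- with(assoc, sum(p_adj < 0.05 & direction == "up"))
message(sprintf("case/control: %d of %d gene-cohort tests significant and up",
                sig_up, nrow(assoc)))

gfr <- do.call(rbind, lapply(cohorts, function(co) {
  do.call(rbind, lapply(genes, function(g) {
    ct <- correlate_clinical(co$expression[, g], co$gfr)
    data.frame(gene = g, cohort_id = co$cohort_id, r = ct$r, p = ct$p)
  }))
}))
utils::write.table(gfr, "results/gfr_correlations.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("GFR: median r = %.2f (%d%% of correlations negative)",
                stats::median(gfr$r), round(100 * mean(gfr$r < 0))))

stages <- do.call(rbind, lapply(cohorts, function(co) {
  st <- compare_stages(co$expression[, genes[1]], co$stage)
  cbind(cohort_id = co$cohort_id, gene = genes[1], st$pairwise,
        trend = st$trend$statistic)
}))
utils::write.table(stages, "results/stage_comparisons.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("stage trend statistics by cohort: %s",
                paste(sprintf("%.2f", unique(stages$trend)),
                      collapse = ", ")))

modules <- read_gmt("results/modules.gmt")
universe <- readLines("results/data/sc/genes.tsv")
ora <- ora_hypergeometric(intersect(modules[[1]], universe),
                          lapply(sets, intersect, universe), universe)
utils::write.table(ora, "results/ora.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sprintf("ORA of module %s: top set %s (p_adj = %.2g)",
                names(modules)[1], ora$set_name[1], ora$p_adj[1]))
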