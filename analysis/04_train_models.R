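#!/usr/bin/env Rscript
# Stage 4: the selector x classifier combination framework. Harmonizes the
# four bulk cohorts, intersects each meta-program with each curated gene
# set into feature panels, enumerates all selector x classifier
# combinations from the full 12-algorithm registry, trains on the pooled
# training cohorts, and ranks every model by validation concordance index.

suppressMessages(library(lnmeta))

seed <- 1L
cohorts <- lapply(1:4, function(i) {
  read_bulk_cohort("results/data/bulk", sprintf("cohort%d", i),
                   role = if (i <= 2) "train" else "validation")
})
cohorts <- harmonize_cohorts(cohorts)
train <- Filter(function(x) x$role == "train", cohorts)
validation <- Filter(function(x) x$role == "validation", cohorts)

sets <- read_gmt("results/data/gene_sets.gmt")
mp_sets <- read_gmt("results/metaprograms.gmt")
bulk_genes <- colnames(cohorts[[1]]$expression)

panels <- list()
for (mp_id in names(mp_sets)) {
  mp <- structure(list(mp_id = mp_id, member_programs = mp_id,
                       top_genes = mp_sets[[mp_id]],
                       mean_internal_correlation = NA),
                  class = "meta_program")
  for (nm in names(sets)) {
    p <- intersect_panel(mp, intersect(sets[[nm]], bulk_genes),
                         set_name = nm)
    if (p$usable && length(p$genes) >= 3) panels[[p$panel_id]] <- p
  }
}
message(sprintf("usable panels: %s",
                paste(sprintf("%s(%d)", names(panels),
                              vapply(panels, function(p) length(p$genes),
                                     integer(1))), collapse = ", ")))

registry <- default_algorithm_registry()
results <- list()
for (p in panels) {
  for (spec in enumerate_combinations(registry, p)) {
    results[[length(results) + 1L]] <-
      suppressWarnings(fit_and_score(spec, train, validation,
                                     seed = derive_seed(seed,
                                                        8000L + length(results))))
  }
}
lb <- build_leaderboard(results)
utils::write.table(lb, "results/leaderboard.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
failed <- sum(is.na(lb$mean_validation_cindex))
message(sprintf("trained %d models (%d failed on degenerate panels)",
                nrow(lb), failed))
message("top five combinations by validation C-index:")
print(utils::head(lb[, c("model", "panel", "n_selected", "mean_cindex",
                         "mean_validation_cindex")], 5), row.names = FALSE)
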