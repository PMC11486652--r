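#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic substrate — a single-cell count
# matrix with four planted leukocyte activity programs, four case/control
# bulk cohorts whose disease signal lives on program 1's genes, and a
# curated-style gene-set collection (one set per program, 20% decoys).
# Everything downstream is recoverable ground truth.

suppressMessages(library(lnmeta))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- sc_sim_params(n_cells = 2000, n_genes = 1000, n_cell_types = 4,
                    markers_per_type = 25, n_programs = 4,
                    genes_per_program = 30, program_activity_fraction = 0.3,
                    effect_log2fc = 2, seed = derive_seed(seed, 1L))
sim <- generate_sc_dataset(sc)
write_count_matrix(sim$counts, file.path(out, "sc"))
message(sprintf("single cell: %d genes x %d cells, %d planted programs",
                nrow(sim$counts$counts), ncol(sim$counts$counts),
                sc$n_programs))

bulk <- bulk_sim_params(n_cohorts = 4, samples_per_arm = 30, n_genes = 1000,
                        signal_genes = sim$truth$program_gene_sets[[1]],
                        delta = 1.5, gfr_beta = 1, stage_beta = 1.5,
                        seed = derive_seed(seed, 2L))
cohorts <- generate_bulk_cohorts(bulk)
for (co in cohorts) write_bulk_cohort(co, file.path(out, "bulk"))
message(sprintf("bulk: %d cohorts x %d samples (%s roles)",
                length(cohorts), nrow(cohorts[[1]]$expression),
                paste(unique(vapply(cohorts, `[[`, "", "role")),
                      collapse = "/")))

sets <- generate_gene_set_collection(sim$truth, contamination = 0.2,
                                     seed = derive_seed(seed, 3L))
write_gmt(sets, file.path(out, "gene_sets.gmt"))
message(sprintf("gene sets: %s",
                paste(sprintf("%s(%d)", names(sets), lengths(sets)),
                      collapse = ", ")))
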