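#!/usr/bin/env Rscript
# Stage 2: single-cell preprocessing — QC filtering, log normalization,
# highly-variable-gene selection, PCA, graph clustering and a t-SNE layout,
# with one-vs-rest marker ranking per cluster. Consumes the matrix written
# by stage 1 and writes the cluster/marker tables.

suppressMessages(library(lnmeta))

seed <- 1L
counts <- read_count_matrix("results/data/sc", "mtx_triplet")
message(sprintf("loaded %d genes x %d cells", nrow(counts$counts),
                ncol(counts$counts)))

filtered <- qc_filter(counts, min_genes_per_cell = 100,
                      max_genes_per_cell = NULL, min_cells_per_gene = 3)
message(sprintf("QC kept %d genes x %d cells", nrow(filtered$counts),
                ncol(filtered$counts)))

norm <- normalize_log(filtered)
hvg <- select_hvg(norm, 300)
pca <- pca_embed(hvg, n_components = 20)
message(sprintf("PC1-PC3 explain %.1f%% of variance",
                100 * sum(pca$explained_var[1:3])))

clusters <- cluster_cells(pca$embedding, n_neighbors = 15,
                          resolution = 0.3, seed = derive_seed(seed, 4L))
clusters$embedding <- tsne_embed(pca$embedding, perplexity = 30,
                                 seed = derive_seed(seed, 5L))
message(sprintf("%d graph communities", length(unique(clusters$labels))))

markers <- rank_markers(hvg, clusters)
dir.create("results", showWarnings = FALSE)
utils::write.table(markers, "results/markers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(cell_id = filtered$cell_ids, cluster = clusters$labels,
             tsne1 = clusters$embedding[, 1],
             tsne2 = clusters$embedding[, 2]),
  "results/clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
top <- markers[markers$p_adj < 0.05 & markers$effect > 0, ]
message(sprintf("%d significant positive markers across clusters (BH < 0.05)",
                nrow(top)))
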