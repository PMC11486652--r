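test_that("qc_filter honors bounds, is idempotent, and keeps order", {
  m <- matrix(c(2L, 0L, 1L,
                1L, 3L, 0L,
                4L, 5L, 0L), 3, 3, byrow = TRUE)
  cm <- toy_counts(m)
  # c3 detects only one gene
  out <- qc_filter(cm, min_genes_per_cell = 2, max_genes_per_cell = Inf,
                   min_cells_per_gene = 0)
  expect_equal(out$cell_ids, c("c1", "c2"))
  expect_equal(out$gene_ids, c("g1", "g2", "g3"))

  # permissive thresholds are the identity
  expect_equal(qc_filter(cm, 0, Inf, 0)$counts, cm$counts)

  # idempotence on a larger random matrix
  set.seed(1)
  big <- toy_counts(matrix(rpois(50 * 40, 0.6), 50, 40))
  once <- qc_filter(big, 3, Inf, 2)
  twice <- qc_filter(once, 3, Inf, 2)
  expect_identical(once$counts, twice$counts)

  expect_error(qc_filter(cm, 10, Inf, 0), "removed everything")
})

test_that("log normalization matches its closed form and is depth-invariant", {
  cm <- toy_counts(matrix(c(2L, 3L, 5L), 3, 1))
  norm <- normalize_log(cm, scale = 10)
  expect_equal(unname(norm$values[, 1]), log1p(c(2, 3, 5)))
  expect_equal(sum(expm1(norm$values[, 1])), 10)

  # all-equal counts within a cell normalize to a constant
  eq <- toy_counts(matrix(4L, 5, 2))
  expect_equal(stats::sd(normalize_log(eq)$values[, 1]), 0)

  # doubling one cell's counts leaves its normalized values unchanged
  set.seed(2)
  m <- matrix(rpois(30, 5) + 1L, 6, 5,
              dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:5)))
  n1 <- normalize_log(count_matrix(m))
  m2 <- m; m2[, 3] <- m2[, 3] * 2L
  n2 <- normalize_log(count_matrix(m2))
  expect_equal(n1$values[, 3], n2$values[, 3], tolerance = 1e-12)

  zero <- toy_counts(matrix(c(1L, 2L, 0L, 0L), 2, 2))
  expect_error(normalize_log(zero), "library size")
})

test_that("HVG selection recovers planted variable genes and tolerates ties", {
  p <- sc_sim_params(n_cells = 800, n_genes = 400, n_cell_types = 1,
                     markers_per_type = 1, n_programs = 3,
                     genes_per_program = 20, effect_log2fc = 2, seed = 3)
  sim <- generate_sc_dataset(p)
  norm <- normalize_log(qc_filter(sim$counts, 5, Inf, 3))
  hv <- select_hvg(norm, 100)
  prog <- intersect(unlist(sim$truth$program_gene_sets), norm$gene_ids)
  overlap <- length(intersect(prog, hv$gene_ids))
  p_enrich <- stats::phyper(overlap - 1, length(prog),
                            length(norm$gene_ids) - length(prog), 100,
                            lower.tail = FALSE)
  expect_lt(p_enrich, 0.01)

  # identity when asking for everything
  expect_setequal(select_hvg(norm, nrow(norm$values))$gene_ids,
                  norm$gene_ids)

  # fully degenerate input: deterministic tie-break, no error
  const <- normalize_log(toy_counts(matrix(3L, 30, 10)))
  expect_equal(select_hvg(const, 5)$gene_ids,
               sort(rownames(const$values))[1:5])
})

test_that("PCA ordering, sign convention, and separation recovery hold", {
  # exact line in gene space
  t_vals <- seq(-2, 2, length.out = 40)
  line <- outer(t_vals, c(1, 2, 3)) + 5
  rownames(line) <- sprintf("cell%d", 1:40)
  pc <- pca_embed(line, n_components = 2)
  expect_gte(pc$explained_var[1], 0.999)
  expect_true(all(diff(pc$explained_var) <= 1e-12))
  expect_lte(sum(pc$explained_var), 1 + 1e-9)

  # 2-type simulation: PC1 separates the types
  p <- sc_sim_params(n_cells = 400, n_genes = 200, n_cell_types = 2,
                     markers_per_type = 30, n_programs = 1,
                     genes_per_program = 5, effect_log2fc = 3,
                     program_activity_fraction = 0.5, seed = 4)
  sim <- generate_sc_dataset(p)
  norm <- normalize_log(qc_filter(sim$counts, 5, Inf, 3))
  emb <- pca_embed(norm, n_components = 2)$embedding
  km <- stats::kmeans(emb[, 1], centers = 2, nstart = 10)
  agree <- max(mean((km$cluster == 1) ==
                      (sim$truth$type_labels == "type1")),
               mean((km$cluster == 2) ==
                      (sim$truth$type_labels == "type1")))
  expect_gte(agree, 0.95)
})

test_that("graph clustering finds well-separated blobs and respects limits", {
  set.seed(5)
  blob1 <- matrix(rnorm(60 * 2, 0, 1), 60, 2)
  blob2 <- matrix(rnorm(60 * 2, 20, 1), 60, 2)
  emb <- rbind(blob1, blob2)
  cl <- cluster_cells(emb, n_neighbors = 15, resolution = 0.2, seed = 1)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(length(unique(cl$labels[1:60])), 1)
  expect_equal(length(unique(cl$labels[61:120])), 1)

  # single cloud at vanishing resolution collapses to one community
  one <- cluster_cells(blob1, n_neighbors = 10, resolution = 0.01, seed = 1)
  expect_equal(length(unique(one$labels)), 1)

  # permutation invariance up to relabeling
  perm <- sample(nrow(emb))
  cl2 <- cluster_cells(emb[perm, ], n_neighbors = 15, resolution = 0.2,
                       seed = 1)
  tab <- table(cl$labels[perm], cl2$labels)
  expect_equal(sum(apply(tab, 1, max)), nrow(emb))

  expect_error(cluster_cells(emb, n_neighbors = 500), "n_neighbors")
})

test_that("graph clustering recovers planted cell types with high ARI", {
  p <- sc_sim_params(n_cells = 600, n_genes = 300, n_cell_types = 4,
                     markers_per_type = 20, n_programs = 1,
                     genes_per_program = 5, effect_log2fc = 2, seed = 6)
  sim <- generate_sc_dataset(p)
  norm <- normalize_log(qc_filter(sim$counts, 5, Inf, 3))
  emb <- pca_embed(norm, 10)$embedding
  cl <- cluster_cells(emb, n_neighbors = 15, resolution = 1, seed = 1)
  tab <- table(cl$labels, sim$truth$type_labels)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  expected <- b * cc / choose(sum(tab), 2)
  ari <- (a - expected) / ((b + cc) / 2 - expected)
  expect_gte(ari, 0.8)
})

test_that("t-SNE layout is finite, seed-stable, and geometry-preserving", {
  set.seed(6)
  emb <- rbind(matrix(rnorm(50 * 3), 50, 3),
               matrix(rnorm(50 * 3, 12), 50, 3))
  y1 <- tsne_embed(emb, perplexity = 10, seed = 3)
  y2 <- tsne_embed(emb, perplexity = 10, seed = 3)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(100, 2))
  expect_true(all(is.finite(y1)))

  intra <- mean(stats::dist(y1[1:50, ]))
  inter <- mean(as.matrix(stats::dist(y1))[1:50, 51:100])
  expect_gt(inter, intra)

  expect_error(tsne_embed(emb[1:10, ], perplexity = 10), "perplexity")
})

test_that("marker ranking surfaces planted markers and behaves under the null", {
  p <- sc_sim_params(n_cells = 300, n_genes = 150, n_cell_types = 2,
                     markers_per_type = 8, n_programs = 1,
                     genes_per_program = 5, effect_log2fc = 3, seed = 8)
  sim <- generate_sc_dataset(p)
  norm <- normalize_log(qc_filter(sim$counts, 5, Inf, 3))
  truth_cl <- as.integer(factor(sim$truth$type_labels)) - 1L
  clusters <- structure(list(labels = truth_cl, parameters = list(),
                             embedding = NULL),
                        class = "cluster_assignment")
  tab <- rank_markers(norm, clusters)
  for (t in 1:2) {
    top10 <- head(tab$gene[tab$cluster == (t - 1L) & tab$effect > 0], 10)
    expect_gte(length(intersect(top10, sim$truth$marker_sets[[t]])), 5)
  }
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))

  # identical expression across clusters: nothing significant
  m <- matrix(rep(rpois(40, 5), 30), 40, 30,
              dimnames = list(sprintf("g%d", 1:40), sprintf("c%d", 1:30)))
  null_norm <- normalize_log(count_matrix(m))
  null_cl <- structure(list(labels = rep(0:1, 15), parameters = list(),
                            embedding = NULL),
                       class = "cluster_assignment")
  null_tab <- rank_markers(null_norm, null_cl)
  expect_equal(sum(null_tab$p_adj < 0.05), 0)
})
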