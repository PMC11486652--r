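#' Quality-control filter on cells and genes
#'
#' Removes cells whose detected-gene count (genes with at least one count)
#' falls outside `[min_genes_per_cell, max_genes_per_cell]` and genes
#' detected in fewer than `min_cells_per_gene` cells, iterating to a fixed
#' point so both conditions hold simultaneously on the returned matrix. The
#' operation is idempotent and preserves row/column order.
#'
#' @param cm a [count_matrix()].
#' @param min_genes_per_cell,max_genes_per_cell detected-gene bounds per
#'   cell; defaults 200 and the 99th percentile of detected-gene counts.
#' @param min_cells_per_gene minimum cells a gene must be detected in
#'   (default 3).
#' @return the filtered [count_matrix()].
#' @export
qc_filter <- function(cm, min_genes_per_cell = 200,
                      max_genes_per_cell = NULL, min_cells_per_gene = 3) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- cm$counts
  if (is.null(max_genes_per_cell)) {
    max_genes_per_cell <- stats::quantile(colSums(m > 0), 0.99, names = FALSE)
  }
  abort_if(min_genes_per_cell < 0 || min_cells_per_gene < 0,
           "thresholds must be nonnegative")
  abort_if(min_genes_per_cell > max_genes_per_cell,
           "min_genes_per_cell must not exceed max_genes_per_cell")
  n0 <- dim(m)
  repeat {
    det_per_cell <- colSums(m > 0)
    keep_cells <- det_per_cell >= min_genes_per_cell &
      det_per_cell <= max_genes_per_cell
    m2 <- m[, keep_cells, drop = FALSE]
    keep_genes <- rowSums(m2 > 0) >= min_cells_per_gene
    m2 <- m2[keep_genes, , drop = FALSE]
    if (identical(dim(m2), dim(m))) break
    m <- m2
  }
  if (nrow(m) == 0L || ncol(m) == 0L) {
    stop(sprintf(paste0("qc_filter removed everything: started with %d genes",
                        " x %d cells, ended %d x %d"),
                 n0[1], n0[2], nrow(m), ncol(m)), call. = FALSE)
  }
  meta <- cm$cell_meta[match(colnames(m), cm$cell_meta$cell_id), ,
                       drop = FALSE]
  rownames(meta) <- NULL
  count_matrix(m, cell_meta = meta)
}

#' Library-size log normalization
#'
#' `value(g, c) = log(1 + scale * count(g, c) / libsize(c))`, the standard
#' counts-per-`scale` log transform; column sums of `expm1(value)` equal
#' `scale` exactly.
#'
#' @param cm a [count_matrix()].
#' @param scale library-size target (default 1e4).
#' @return a `normalized_matrix`: `values` (genes x cells), `gene_ids`,
#'   `cell_ids`, `cell_meta`, `normalization` record.
#' @export
normalize_log <- function(cm, scale = 1e4) {
  stopifnot(inherits(cm, "count_matrix"))
  lib <- colSums(cm$counts)
  abort_if(any(lib == 0), "zero library size; run qc_filter first")
  v <- log1p(sweep(as.matrix(cm$counts), 2L, scale / lib, "*"))
  structure(list(values = v, gene_ids = rownames(v), cell_ids = colnames(v),
                 cell_meta = cm$cell_meta,
                 normalization = list(scale = scale, log_base = exp(1),
                                      hvg = NULL)),
            class = "normalized_matrix")
}

#' Select highly variable genes by standardized dispersion
#'
#' Dispersion is variance/mean of the back-transformed (`expm1`) values,
#' z-scored within 20 equal-frequency mean bins; the `n_top` genes with the
#' highest standardized dispersion are retained. Ties (including fully
#' degenerate input) break deterministically by gene symbol order.
#'
#' @param norm a `normalized_matrix`.
#' @param n_top number of genes to keep (`<=` number of genes).
#' @return the `normalized_matrix` restricted to the selected genes, with
#'   the selection recorded under `normalization$hvg`.
#' @export
select_hvg <- function(norm, n_top) {
  stopifnot(inherits(norm, "normalized_matrix"))
  g <- nrow(norm$values)
  abort_if(n_top > g, "n_top exceeds the number of genes")
  x <- expm1(norm$values)
  mu <- rowMeans(x)
  va <- apply(x, 1L, stats::var)
  disp <- ifelse(mu > 0, va / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = 20L, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, rownames(norm$values))
  keep <- sort(ord[seq_len(n_top)])
  out <- norm
  out$values <- norm$values[keep, , drop = FALSE]
  out$gene_ids <- rownames(out$values)
  out$normalization$hvg <- rownames(out$values)
  out
}

#' PCA embedding of cells
#'
#' Principal components of the gene-centered cells x genes matrix, ordered
#' by decreasing explained variance. The sign of each component is fixed by
#' making its largest-magnitude gene loading positive.
#'
#' @param norm a `normalized_matrix` (genes x cells) or a plain cells x
#'   genes matrix.
#' @param n_components number of components (`<= min(genes, cells)`).
#' @return list with `embedding` (cells x n_components), `explained_var`
#'   (fractions of total variance, non-increasing), `loadings`.
#' @export
pca_embed <- function(norm, n_components = 30) {
  x <- if (inherits(norm, "normalized_matrix")) t(norm$values) else as.matrix(norm)
  abort_if(n_components > min(dim(x)),
           "n_components exceeds min(genes, cells)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  total_var <- sum(apply(x, 2L, stats::var))
  list(embedding = sweep(pc$x, 2L, flip, "*"),
       explained_var = pc$sdev[seq_len(n_components)]^2 / total_var,
       loadings = sweep(pc$rotation, 2L, flip, "*"))
}

#' Graph-based clustering of cells
#'
#' Builds a k-nearest-neighbor graph on the embedding, weights edges by the
#' Jaccard similarity of the endpoint neighborhoods (shared-nearest-neighbor
#' weighting), and partitions it by greedy modularity optimization with a
#' resolution parameter. Deterministic given `seed`; labels are contiguous
#' from 0 and ordered by decreasing cluster size.
#'
#' @param embedding cells x d numeric matrix.
#' @param n_neighbors neighbors per cell (`< n_cells`; default 15).
#' @param resolution modularity resolution (default 1.0).
#' @param seed integer seed.
#' @return a `cluster_assignment`: `labels` (0-based integers),
#'   `parameters`, `embedding` slot (2-D layout, filled by the caller).
#' @export
cluster_cells <- function(embedding, n_neighbors = 15, resolution = 1.0,
                          seed = 1L) {
  n <- nrow(embedding)
  abort_if(n_neighbors >= n, "n_neighbors must be < n_cells")
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(n_neighbors)]))
  nn_sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))

  ii <- rep(seq_len(n), each = n_neighbors)
  jj <- as.vector(t(nn))
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  w <- vapply(seq_along(a), function(e) {
    s1 <- nn_sets[[a[e]]]; s2 <- nn_sets[[b[e]]]
    length(intersect(s1, s2)) / length(union(s1, s2))
  }, numeric(1))
  pos <- w > 0
  g <- igraph::graph_from_edgelist(cbind(a[pos], b[pos]), directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = w[pos])

  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(memb)])
  structure(list(labels = as.integer(labels),
                 parameters = list(n_neighbors = n_neighbors,
                                   resolution = resolution, seed = seed),
                 embedding = NULL),
            class = "cluster_assignment")
}

#' 2-D t-SNE layout for visualization
#'
#' A thin deterministic wrapper; no downstream computation depends on the
#' coordinates.
#'
#' @param embedding cells x d numeric matrix (typically PCA).
#' @param perplexity t-SNE perplexity, `< (n_cells - 1) / 3` (default 30).
#' @param seed integer seed.
#' @return cells x 2 numeric matrix.
#' @export
tsne_embed <- function(embedding, perplexity = 30, seed = 1L) {
  n <- nrow(embedding)
  abort_if(perplexity >= (n - 1) / 3,
           "perplexity must be < (n_cells - 1) / 3")
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(as.matrix(embedding), dims = 2,
                      perplexity = perplexity, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE)
  out <- fit$Y
  rownames(out) <- rownames(embedding)
  out
}

# vectorized one-vs-rest rank-sum test (normal approximation with tie
# correction) for every gene at once
ranksum_one_vs_rest <- function(values, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  rk <- t(apply(values, 1L, rank))
  w <- rowSums(rk[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  tie_term <- apply(values, 1L, function(v) {
    tt <- table(v)
    sum(tt^3 - tt)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- ifelse(sigma2 > 0, (w - n1 * n2 / 2) / sqrt(sigma2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  pmin(1, p)
}

#' Per-cluster marker ranking
#'
#' One-vs-rest rank-sum test per gene per cluster with Benjamini-Hochberg
#' adjustment within each cluster; rows sorted by raw p then effect size
#' (difference of mean normalized expression, cluster minus rest).
#' Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param norm a `normalized_matrix`.
#' @param clusters a `cluster_assignment` over the same cells.
#' @return data frame with columns `cluster`, `gene`, `effect`, `p_raw`,
#'   `p_adj`.
#' @export
rank_markers <- function(norm, clusters) {
  stopifnot(inherits(norm, "normalized_matrix"),
            inherits(clusters, "cluster_assignment"))
  labels <- clusters$labels
  abort_if(length(unique(labels)) < 2L, "need at least 2 clusters")
  v <- norm$values
  out <- lapply(sort(unique(labels)), function(cl) {
    in_cl <- labels == cl
    if (sum(in_cl) < 3L) {
      warning(sprintf("cluster %d has < 3 cells; skipped", cl), call. = FALSE)
      return(NULL)
    }
    p <- ranksum_one_vs_rest(v, in_cl)
    eff <- rowMeans(v[, in_cl, drop = FALSE]) -
      rowMeans(v[, !in_cl, drop = FALSE])
    df <- data.frame(cluster = cl, gene = rownames(v), effect = eff,
                     p_raw = p, p_adj = stats::p.adjust(p, "BH"),
                     stringsAsFactors = FALSE, row.names = NULL)
    df[order(df$p_raw, -df$effect), ]
  })
  do.call(rbind, out)
}
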