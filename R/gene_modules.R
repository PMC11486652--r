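#' Dual ranking of gene contributions to factors
#'
#' Builds the two rank matrices behind the nonoverlapping module assignment:
#' one ranks genes within each factor by their contribution (1 = the factor's
#' strongest gene), the other ranks factors within each gene (1 = the gene's
#' strongest factor). Ties are broken by gene symbol order within a factor
#' and by factor index within a gene, so the result is deterministic and each
#' row/column is an exact permutation.
#'
#' @param spectra k x genes nonnegative matrix with gene colnames.
#' @return a `rank_matrices` object with `gene_within_factor` (k x genes,
#'   rows permutations of 1..genes) and `factor_within_gene` (k x genes,
#'   columns permutations of 1..k).
#' @export
rank_contributions <- function(spectra) {
  spectra <- as.matrix(spectra)
  abort_if(anyNA(spectra), "spectra must not contain NA")
  k <- nrow(spectra); g <- ncol(spectra)
  symbols <- colnames(spectra) %||% sprintf("g%d", seq_len(g))
  sym_order <- order(symbols)
  sym_rank <- integer(g); sym_rank[sym_order] <- seq_len(g)

  gene_within_factor <- matrix(0L, k, g, dimnames = dimnames(spectra))
  for (f in seq_len(k)) {
    o <- order(-spectra[f, ], sym_rank)
    gene_within_factor[f, o] <- seq_len(g)
  }
  factor_within_gene <- matrix(0L, k, g, dimnames = dimnames(spectra))
  for (j in seq_len(g)) {
    o <- order(-spectra[, j], seq_len(k))
    factor_within_gene[o, j] <- seq_len(k)
  }
  structure(list(gene_within_factor = gene_within_factor,
                 factor_within_gene = factor_within_gene),
            class = "rank_matrices")
}

#' Assign genes to nonoverlapping per-factor modules by dual ranking
#'
#' For each factor, genes are traversed in within-factor rank order and
#' collected while the factor remains the gene's rank-1 factor. The moment a
#' gene's contribution to another factor is more significant (its rank-1
#' factor differs), `mode = "stop"` ends the module (the literal "until"
#' reading), while `mode = "skip"` passes over that gene and keeps collecting
#' later assignable ones. Because a gene's rank-1 factor is unique, modules
#' are pairwise disjoint in both modes, and every stop-mode module is a
#' prefix of the corresponding skip-mode module.
#'
#' @param spectra k x genes nonnegative matrix with gene colnames.
#' @param mode `"stop"` (default) or `"skip"`.
#' @return list of `gene_module` objects: `factor_id`, `genes` (ordered by
#'   within-factor rank), `scores` (matching contributions).
#' @export
assign_disjoint_modules <- function(spectra, mode = c("stop", "skip")) {
  mode <- match.arg(mode)
  spectra <- as.matrix(spectra)
  abort_if(min(spectra) < 0, "spectra must be nonnegative")
  rk <- rank_contributions(spectra)
  k <- nrow(spectra)
  symbols <- colnames(spectra) %||% sprintf("g%d", seq_len(ncol(spectra)))
  top_factor <- apply(rk$factor_within_gene, 2L, function(col) which(col == 1L))

  lapply(seq_len(k), function(f) {
    traversal <- order(rk$gene_within_factor[f, ])
    assignable <- top_factor[traversal] == f
    keep <- if (mode == "stop") {
      first_bad <- which(!assignable)[1]
      if (is.na(first_bad)) traversal else traversal[seq_len(first_bad - 1L)]
    } else {
      traversal[assignable]
    }
    structure(list(factor_id = rownames(spectra)[f] %||% sprintf("factor%d", f),
                   genes = symbols[keep],
                   scores = unname(spectra[f, keep])),
              class = "gene_module")
  })
}

#' Pairwise Pearson correlation between program spectra
#'
#' Pools the rows of every spectra matrix in the collection, restricts them
#' to the shared gene universe (intersection of colnames), and returns the
#' symmetric Pearson correlation matrix with unit diagonal. A zero-variance
#' spectrum correlates 0 with everything (with a warning).
#'
#' @param spectra_collection list of k_i x genes matrices with gene colnames;
#'   a single matrix is accepted.
#' @return square correlation matrix named `source.factor`.
#' @export
correlate_programs <- function(spectra_collection) {
  if (is.matrix(spectra_collection)) {
    spectra_collection <- list(pooled = spectra_collection)
  }
  if (is.null(names(spectra_collection))) {
    names(spectra_collection) <- sprintf("src%d", seq_along(spectra_collection))
  }
  shared <- Reduce(intersect, lapply(spectra_collection, colnames))
  abort_if(length(shared) == 0, "shared gene universe is empty")
  pooled <- do.call(rbind, lapply(names(spectra_collection), function(nm) {
    m <- spectra_collection[[nm]][, shared, drop = FALSE]
    rn <- rownames(m) %||% sprintf("factor%d", seq_len(nrow(m)))
    rownames(m) <- paste(nm, rn, sep = ".")
    m
  }))
  abort_if(nrow(pooled) < 2L, "need at least 2 programs")
  sds <- apply(pooled, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance spectrum; its correlations are set to 0",
            call. = FALSE)
  }
  cc <- matrix(0, nrow(pooled), nrow(pooled),
               dimnames = list(rownames(pooled), rownames(pooled)))
  ok <- sds > 0
  if (any(ok)) cc[ok, ok] <- stats::cor(t(pooled[ok, , drop = FALSE]))
  diag(cc) <- 1
  (cc + t(cc)) / 2
}

#' Consolidate correlated programs into meta-programs
#'
#' Average-linkage hierarchical clustering on distance `1 - r`, cut into
#' `n_meta` groups. Each group's top genes are the highest mean-contribution
#' genes across its member spectra; groups are labelled MP1..MPn ordered by
#' size then mean internal correlation.
#'
#' @param corr correlation matrix from [correlate_programs()].
#' @param n_meta number of meta-programs (`<=` number of programs).
#' @param top_n length of each meta-program's top-gene list.
#' @param spectra_collection the same collection passed to
#'   [correlate_programs()].
#' @return list of `meta_program` objects: `mp_id`, `member_programs`,
#'   `top_genes`, `mean_internal_correlation`.
#' @export
cluster_into_metaprograms <- function(corr, n_meta, top_n, spectra_collection) {
  abort_if(n_meta > nrow(corr), "n_meta exceeds the number of programs")
  if (is.matrix(spectra_collection)) {
    spectra_collection <- list(pooled = spectra_collection)
  }
  if (is.null(names(spectra_collection))) {
    names(spectra_collection) <- sprintf("src%d", seq_along(spectra_collection))
  }
  shared <- Reduce(intersect, lapply(spectra_collection, colnames))
  pooled <- do.call(rbind, lapply(names(spectra_collection), function(nm) {
    m <- spectra_collection[[nm]][, shared, drop = FALSE]
    rn <- rownames(m) %||% sprintf("factor%d", seq_len(nrow(m)))
    rownames(m) <- paste(nm, rn, sep = ".")
    l2_normalize_rows(m)
  }))
  pooled <- pooled[rownames(corr), , drop = FALSE]

  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  groups <- stats::cutree(hc, k = n_meta)

  info <- lapply(unique(groups), function(gid) {
    members <- names(groups)[groups == gid]
    sub <- corr[members, members, drop = FALSE]
    mic <- if (length(members) == 1L) 1 else mean(sub[lower.tri(sub)])
    mean_contrib <- colMeans(pooled[members, , drop = FALSE])
    ord <- order(-mean_contrib, colnames(pooled))
    list(members = members, mic = mic,
         top_genes = colnames(pooled)[ord][seq_len(min(top_n, length(ord)))])
  })
  sizes <- vapply(info, function(x) length(x$members), integer(1))
  mics <- vapply(info, function(x) x$mic, numeric(1))
  info <- info[order(-sizes, -mics)]

  lapply(seq_along(info), function(i) {
    structure(list(mp_id = sprintf("MP%d", i),
                   member_programs = info[[i]]$members,
                   top_genes = info[[i]]$top_genes,
                   mean_internal_correlation = info[[i]]$mic),
              class = "meta_program")
  })
}
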