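#' Prepare a normalized matrix for non-negative factorization
#'
#' Negative values are clipped to zero (NMF requires a nonnegative input);
#' optional per-gene variance scaling divides each gene by its standard
#' deviation so highly expressed genes do not dominate the factorization.
#' Zero-variance genes are dropped with a warning when scaling.
#'
#' @param norm a `normalized_matrix` from [normalize_log()] (genes x cells),
#'   or a plain cells x genes matrix.
#' @param variance_scale divide each gene by its SD (default TRUE).
#' @return a cells x genes nonnegative matrix.
#' @export
prepare_matrix <- function(norm, variance_scale = TRUE) {
  x <- if (inherits(norm, "normalized_matrix")) t(norm$values) else as.matrix(norm)
  abort_if(any(!is.finite(x)), "input must be finite")
  x[x < 0] <- 0
  if (variance_scale) {
    sds <- apply(x, 2L, stats::sd)
    drop <- sds == 0 | !is.finite(sds)
    if (any(drop)) {
      warning(sprintf("dropping %d zero-variance gene(s) before scaling",
                      sum(drop)), call. = FALSE)
      x <- x[, !drop, drop = FALSE]
      sds <- sds[!drop]
    }
    x <- sweep(x, 2L, sds, "/")
  }
  abort_if(all(x == 0), "prepared matrix is all zero")
  x
}

#' Fit a single NMF by multiplicative updates
#'
#' Minimizes the Frobenius loss `||X - W H||_F` with the classic
#' multiplicative update rules from uniform random initialization. The loss
#' trace is recorded each iteration and is non-increasing (the core
#' multiplicative-update guarantee); iteration stops when the relative loss
#' change drops below `tol` or at `max_iter`.
#'
#' @param X cells x genes nonnegative matrix.
#' @param k number of components, `<= min(dim(X))`.
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum multiplicative updates (default 500).
#' @param tol relative loss-change stopping threshold (default 1e-5).
#' @return a `factorization`: `W` (cells x k usages), `H` (k x genes
#'   spectra), `k`, `seed`, `loss_trace`.
#' @export
fit_nmf <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-5) {
  abort_if(min(X) < 0, "X must be nonnegative")
  abort_if(k > min(dim(X)), sprintf("k = %d exceeds min(dim(X)) = %d",
                                    k, min(dim(X))))
  n <- nrow(X); g <- ncol(X)
  eps <- .Machine$double.eps
  set.seed(as.integer(seed))
  scale0 <- sqrt(mean(X) / k + eps)
  W <- matrix(stats::runif(n * k), n, k) * scale0
  H <- matrix(stats::runif(k * g), k, g) * scale0

  loss <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    l <- sqrt(sum((X - W %*% H)^2))
    loss <- c(loss, l)
    if (is.finite(prev) && prev > 0 && abs(prev - l) / prev < tol) break
    prev <- l
  }
  structure(list(W = W, H = H, k = as.integer(k), seed = as.integer(seed),
                 loss_trace = loss),
            class = "factorization")
}

# L2-normalize matrix rows; all-zero rows are left as zero
l2_normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# nonnegative least squares refit of usages against fixed spectra
refit_usages_nnls <- function(X, H) {
  A <- t(H) # genes x k
  W <- t(apply(X, 1L, function(x) pracma::lsqnonneg(A, x)$x))
  if (nrow(H) == 1L) W <- matrix(W, ncol = 1L)
  W
}

#' Consensus NMF over replicate factorizations
#'
#' Runs `n_runs` independent factorizations (seeds derived from the master
#' seed), pools all replicate spectra as unit vectors, discards outlier
#' components whose mean Euclidean distance to their `floor(n_runs/3)`
#' nearest neighbors exceeds `density_threshold`, clusters the survivors into
#' `k` groups by seeded k-means, takes the component-wise median of each
#' group as the consensus spectrum (re-normalized), and refits usages by
#' nonnegative least squares against the fixed consensus spectra.
#'
#' @param X cells x genes nonnegative matrix.
#' @param k number of consensus programs.
#' @param n_runs replicate factorizations (>= 2; the pipeline default follows
#'   the 100-replicate consensus convention, scaled by the caller).
#' @param density_threshold outlier filter on the local-density distance
#'   (default 0.5; `Inf` disables filtering).
#' @param seed master seed.
#' @param max_iter,tol forwarded to [fit_nmf()].
#' @return a `consensus_programs`: `consensus_spectra` (k x genes, unit L2
#'   rows), `refit_usages` (cells x k), `k`, `n_runs`, `density_threshold`,
#'   `kept_components`, `component_labels`, `component_spectra`, `stability`
#'   (mean silhouette of the component clustering, cosine distance) and
#'   `rel_error` (relative Frobenius reconstruction error).
#' @export
consensus_factorize <- function(X, k, n_runs = 30L, density_threshold = 0.5,
                                seed = 1L, max_iter = 200L, tol = 1e-4) {
  abort_if(n_runs < 2L, "n_runs must be >= 2")
  fits <- lapply(seq_len(n_runs), function(r) {
    fit_nmf(X, k, seed = derive_seed(seed, 1000L + r),
            max_iter = max_iter, tol = tol)
  })
  pooled <- do.call(rbind, lapply(fits, function(f) l2_normalize_rows(f$H)))

  # density filter: mean distance to the floor(n_runs/3) nearest neighbors
  l_nn <- max(1L, n_runs %/% 3L)
  d2 <- pmax(outer(rowSums(pooled^2), rowSums(pooled^2), "+") -
               2 * tcrossprod(pooled), 0)
  dm <- sqrt(d2)
  diag(dm) <- Inf
  local_dist <- apply(dm, 1L, function(row) mean(sort(row)[seq_len(l_nn)]))
  keep <- local_dist <= density_threshold
  abort_if(!any(keep),
           "all replicate components removed by the density filter")
  kept <- pooled[keep, , drop = FALSE]

  set.seed(derive_seed(seed, 999L))
  km <- stats::kmeans(kept, centers = k, nstart = 10L, iter.max = 100L)

  consensus <- t(vapply(seq_len(k), function(cl) {
    apply(kept[km$cluster == cl, , drop = FALSE], 2L, stats::median)
  }, numeric(ncol(kept))))
  consensus <- l2_normalize_rows(consensus)
  dimnames(consensus) <- list(sprintf("program%d", seq_len(k)), colnames(X))

  stability <- if (k >= 2L && nrow(kept) > k) {
    cosd <- stats::as.dist(1 - tcrossprod(kept))
    mean(cluster::silhouette(km$cluster, cosd)[, "sil_width"])
  } else NA_real_

  W <- refit_usages_nnls(X, consensus)
  rownames(W) <- rownames(X)
  colnames(W) <- rownames(consensus)
  rel_error <- sqrt(sum((X - W %*% consensus)^2)) / sqrt(sum(X^2))

  structure(list(consensus_spectra = consensus, refit_usages = W,
                 k = as.integer(k), n_runs = as.integer(n_runs),
                 density_threshold = density_threshold,
                 kept_components = sum(keep),
                 component_labels = km$cluster, component_spectra = kept,
                 stability = stability, rel_error = rel_error),
            class = "consensus_programs")
}

#' Stability and error diagnostics across a range of k
#'
#' Runs [consensus_factorize()] for each k in `[k_min, k_max]` and records
#' the component-clustering stability (mean silhouette, cosine distance) and
#' the relative Frobenius reconstruction error, mirroring the diagnostic
#' plots used to choose the component number. The k with maximal stability
#' is returned as a suggestion; the choice remains the caller's.
#'
#' @param X cells x genes nonnegative matrix.
#' @param k_min,k_max inclusive range, `2 <= k_min <= k_max`.
#' @param n_runs,density_threshold,seed,max_iter,tol forwarded per k.
#' @return a `k_diagnostics`: data frame `table` with columns `k`,
#'   `stability`, `error`, plus `suggested_k`.
#' @export
k_selection_diagnostics <- function(X, k_min = 4L, k_max = 9L, n_runs = 10L,
                                    density_threshold = 0.5, seed = 1L,
                                    max_iter = 200L, tol = 1e-4) {
  abort_if(!(2L <= k_min && k_min <= k_max), "need 2 <= k_min <= k_max")
  ks <- seq.int(k_min, k_max)
  rows <- lapply(ks, function(k) {
    cp <- consensus_factorize(X, k, n_runs = n_runs,
                              density_threshold = density_threshold,
                              seed = derive_seed(seed, 5000L + k),
                              max_iter = max_iter, tol = tol)
    data.frame(k = k, stability = cp$stability, error = cp$rel_error)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab,
                 suggested_k = tab$k[which.max(tab$stability)]),
            class = "k_diagnostics")
}
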