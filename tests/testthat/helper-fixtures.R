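# shared small fixtures, built in code

# tiny deterministic count matrix with named dims
toy_counts <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("c%d", seq_len(ncol(m)))
  count_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force concordance index: explicit pair enumeration
cindex_bruteforce <- function(scores, labels) {
  cases <- which(labels == 1)
  controls <- which(labels == 0)
  tot <- 0
  for (i in cases) for (j in controls) {
    tot <- tot + if (scores[i] > scores[j]) 1 else
      if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# brute-force ORA p-value: enumerate every possible query of size q from the
# universe and count draws with overlap >= observed
ora_bruteforce <- function(query, set, universe) {
  q <- length(query)
  obs <- length(intersect(query, set))
  draws <- utils::combn(universe, q, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set)) >= obs,
              logical(1)))
}

# optimal component-to-truth matching over all permutations (k small)
best_match_correlations <- function(est, truth) {
  cc <- stats::cor(t(est), t(truth))
  k <- ncol(cc)
  perms <- do.call(rbind, combinat_perms(seq_len(k)))
  best <- -Inf; best_diag <- NULL
  for (i in seq_len(nrow(perms))) {
    d <- cc[cbind(perms[i, ], seq_len(k))]
    if (sum(d) > best) { best <- sum(d); best_diag <- d }
  }
  best_diag
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# harmonized 4-cohort planted-signal setup used by ensemble tests
planted_cohort_setup <- function(delta, samples_per_arm = 30, seed = 1,
                                 gfr_beta = 1, stage_beta = 1.5) {
  p <- bulk_sim_params(n_cohorts = 4, samples_per_arm = samples_per_arm,
                       delta = delta, gfr_beta = gfr_beta,
                       stage_beta = stage_beta, seed = seed)
  cohorts <- harmonize_cohorts(generate_bulk_cohorts(p))
  list(params = p,
       train = Filter(function(x) x$role == "train", cohorts),
       validation = Filter(function(x) x$role == "validation", cohorts),
       all = cohorts)
}
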