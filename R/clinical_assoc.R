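#' Case/control expression tests for a gene list
#'
#' Per-gene two-sided test of cases versus controls (rank-sum by default,
#' Welch's t by flag), Benjamini-Hochberg adjustment across the supplied
#' list, direction from the sign of the case-minus-control location
#' difference. Constant genes get p = 1 and direction "none" with a warning.
#'
#' @param cohort a `bulk_cohort` with both classes of >= 3 samples.
#' @param genes character vector of genes present in the cohort.
#' @param test `"ranksum"` (default) or `"welch"`.
#' @return data frame with `gene`, `cohort_id`, `test`, `statistic`,
#'   `p_raw`, `p_adj`, `direction`.
#' @export
case_control_test <- function(cohort, genes, test = c("ranksum", "welch")) {
  test <- match.arg(test)
  stopifnot(inherits(cohort, "bulk_cohort"))
  y <- cohort$labels
  abort_if(sum(y == 1L) < 3L || sum(y == 0L) < 3L,
           "need >= 3 samples in each class")
  abort_if(!all(genes %in% colnames(cohort$expression)),
           "some genes are absent from the cohort")
  rows <- lapply(genes, function(g) {
    x1 <- cohort$expression[y == 1L, g]
    x0 <- cohort$expression[y == 0L, g]
    if (stats::sd(c(x1, x0)) == 0) {
      warning(sprintf("gene %s is constant; p set to 1", g), call. = FALSE)
      return(data.frame(gene = g, cohort_id = cohort$cohort_id, test = test,
                        statistic = 0, p_raw = 1, direction = "none",
                        stringsAsFactors = FALSE))
    }
    if (test == "ranksum") {
      ht <- suppressWarnings(stats::wilcox.test(x1, x0))
      delta <- stats::median(x1) - stats::median(x0)
    } else {
      ht <- stats::t.test(x1, x0)
      delta <- mean(x1) - mean(x0)
    }
    data.frame(gene = g, cohort_id = cohort$cohort_id, test = test,
               statistic = unname(ht$statistic), p_raw = ht$p.value,
               direction = if (delta > 0) "up" else if (delta < 0) "down"
                           else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, "BH")
  out[, c("gene", "cohort_id", "test", "statistic", "p_raw", "p_adj",
          "direction")]
}

#' Correlate gene expression with a clinical covariate
#'
#' Pairs with a missing covariate value are dropped (count reported in the
#' `"n_dropped"` attribute). Spearman is the default, matching the skewed
#' clinical distributions the generator emulates; Pearson by flag.
#'
#' @param expr per-sample numeric expression values.
#' @param covariate per-sample numeric covariate (e.g. GFR); may contain NA.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `r`, `p`, `n` (pairs used).
#' @export
correlate_clinical <- function(expr, covariate,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  abort_if(length(expr) != length(covariate), "length mismatch")
  ok <- is.finite(expr) & is.finite(covariate)
  abort_if(sum(ok) < 4L, "need >= 4 paired non-missing values")
  abort_if(stats::sd(expr[ok]) == 0 || stats::sd(covariate[ok]) == 0,
           "constant vector")
  ht <- suppressWarnings(stats::cor.test(expr[ok], covariate[ok],
                                         method = method))
  out <- list(r = unname(ht$estimate), p = ht$p.value, n = sum(ok))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Compare expression across ordinal pathological stages
#'
#' Pairwise two-sided rank-sum tests between all stage pairs with BH
#' adjustment, plus a Jonckheere-style trend statistic: the rank correlation
#' between expression and the ordinal stage rank (II < III < IV).
#' Stages with fewer than 3 samples are excluded with a warning.
#'
#' @param expr per-sample numeric expression values.
#' @param stage per-sample ordered factor or character in II/III/IV.
#' @return list with `pairwise` (data frame: `pair`, `statistic`, `p_raw`,
#'   `p_adj`) and `trend` (list `statistic`, `p`): positive statistic means
#'   expression increases with stage.
#' @export
compare_stages <- function(expr, stage) {
  stage <- factor(as.character(stage), levels = c("II", "III", "IV"))
  ok <- !is.na(stage) & is.finite(expr)
  expr <- expr[ok]; stage <- droplevels(stage[ok])
  tab <- table(stage)
  small <- names(tab)[tab < 3L]
  if (length(small) > 0) {
    warning(sprintf("stage(s) %s have < 3 samples; excluded",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(as.character(stage) %in% small)
    expr <- expr[keep]; stage <- droplevels(stage[keep])
  }
  lv <- levels(stage)
  abort_if(length(lv) < 2L, "need >= 2 stages with >= 3 samples each")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    xa <- expr[stage == pr[1]]; xb <- expr[stage == pr[2]]
    ht <- suppressWarnings(stats::wilcox.test(xb, xa))
    data.frame(pair = paste(pr[2], "vs", pr[1]),
               statistic = unname(ht$statistic), p_raw = ht$p.value,
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$p_adj <- stats::p.adjust(pw$p_raw, "BH")
  tr <- suppressWarnings(stats::cor.test(expr, as.integer(stage),
                                         method = "kendall"))
  list(pairwise = pw,
       trend = list(statistic = unname(tr$estimate), p = tr$p.value))
}

#' Hypergeometric over-representation analysis against a gene universe
#'
#' Per set, the upper-tail hypergeometric probability of observing at least
#' the actual overlap between the query and the set (both intersected with
#' the universe), BH-adjusted across the collection and sorted by raw p.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param collection named list of gene sets.
#' @param universe character vector defining the testable gene space.
#' @return data frame with `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_raw`, `p_adj`.
#' @export
ora_hypergeometric <- function(query, collection, universe) {
  universe <- unique(universe)
  abort_if(length(universe) == 0L, "empty universe")
  query <- unique(query)
  abort_if(!all(query %in% universe), "query must be a subset of universe")
  n_u <- length(universe); n_q <- length(query)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    ov <- length(intersect(query, s))
    # P(X >= ov), X ~ Hypergeom(white = |set|, black = |universe \ set|, draws = |query|)
    p <- stats::phyper(ov - 1, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap = ov, set_size = length(s),
               query_size = n_q, universe_size = n_u, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, "BH")
  out[order(out$p_raw), , drop = FALSE]
}

#' Exclusive intersection sizes of a family of gene sets
#'
#' For every nonempty subset of set names, the number of genes belonging to
#' exactly those sets (the cells of an UpSet diagram); exclusive counts sum
#' to the union size.
#'
#' @param sets named list of >= 2 gene sets.
#' @return data frame with `combination` (names joined by `&`), `degree`,
#'   `count`, including zero-count combinations.
#' @export
set_intersection_counts <- function(sets) {
  abort_if(length(sets) < 2L, "need >= 2 sets")
  abort_if(is.null(names(sets)), "sets must be named")
  nms <- names(sets)
  union_all <- unique(unlist(sets))
  membership <- vapply(sets, function(s) union_all %in% s,
                       logical(length(union_all)))
  if (length(union_all) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(row) paste(nms[row], collapse = "&"))
  combos <- unlist(lapply(seq_along(nms), function(d) {
    utils::combn(nms, d, FUN = paste, collapse = "&")
  }))
  counts <- vapply(combos, function(cb) sum(key == cb), integer(1))
  data.frame(combination = combos,
             degree = lengths(strsplit(combos, "&", fixed = TRUE)),
             count = unname(counts), stringsAsFactors = FALSE)
}
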