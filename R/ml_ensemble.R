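#' Concordance index of a score vector against binary labels
#'
#' Over all case-control pairs, a concordant pair (case scored higher)
#' counts 1, a tied pair 0.5, a discordant pair 0; the returned fraction
#' equals the area under the ROC curve for binary outcomes. Computed via the
#' rank-sum identity, which handles ties exactly.
#'
#' @param scores numeric per-sample scores (higher = more case-like).
#' @param labels binary 0/1 labels, both classes present.
#' @return the C-index in `[0, 1]`.
#' @export
concordance_index <- function(scores, labels) {
  labels <- as.integer(labels)
  abort_if(length(scores) != length(labels), "length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  abort_if(n1 == 0L || n0 == 0L, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Harmonize bulk cohorts onto a shared, per-cohort standardized gene space
#'
#' Restricts every cohort to the intersection of gene sets and z-scores each
#' gene within each cohort (mean 0, SD 1), the merge convention used before
#' pooling training cohorts. Genes with zero variance in any cohort are
#' dropped everywhere with a warning.
#'
#' @param cohorts list of `bulk_cohort` objects.
#' @return the harmonized list.
#' @export
harmonize_cohorts <- function(cohorts) {
  abort_if(length(cohorts) < 1L, "need at least one cohort")
  shared <- Reduce(intersect, lapply(cohorts, function(co) colnames(co$expression)))
  abort_if(length(shared) == 0L, "empty gene intersection across cohorts")
  zero_var <- Reduce(union, lapply(cohorts, function(co) {
    sds <- apply(co$expression[, shared, drop = FALSE], 2L, stats::sd)
    shared[sds == 0]
  }))
  if (length(zero_var) > 0) {
    warning(sprintf("dropping %d zero-variance gene(s) in all cohorts",
                    length(zero_var)), call. = FALSE)
    shared <- setdiff(shared, zero_var)
    abort_if(length(shared) == 0L, "no genes left after zero-variance drop")
  }
  lapply(cohorts, function(co) {
    e <- co$expression[, shared, drop = FALSE]
    co$expression <- scale(e)
    attr(co$expression, "scaled:center") <- NULL
    attr(co$expression, "scaled:scale") <- NULL
    co
  })
}

#' Intersect a meta-program with a curated gene set into a feature panel
#'
#' @param mp a `meta_program`.
#' @param gene_set character vector of genes.
#' @param set_name name for provenance (default from the vector's name).
#' @return a `feature_panel`: `panel_id`, `genes` (meta-program order),
#'   `provenance`, `usable` flag (FALSE when the intersection is empty).
#' @export
intersect_panel <- function(mp, gene_set, set_name = "set") {
  stopifnot(inherits(mp, "meta_program"))
  genes <- mp$top_genes[mp$top_genes %in% gene_set]
  structure(list(panel_id = paste(mp$mp_id, set_name, sep = "x"),
                 genes = genes,
                 provenance = list(mp_id = mp$mp_id, set_name = set_name),
                 usable = length(genes) > 0L),
            class = "feature_panel")
}

#' The default selector/classifier algorithm registry
#'
#' Mirrors the study's twelve algorithm families: three penalized linear
#' models (LASSO, Ridge, elastic net), stepwise logistic search in three
#' directions, componentwise linear boosting (the glmBoost family),
#' linear discriminant analysis, partial-least-squares logistic regression,
#' a probability random forest (the classification analogue of the random
#' survival forest, since the outcome here is binary disease status),
#' stochastic gradient-boosted trees (classic GBM settings on the xgboost
#' engine), XGBoost, a radial-kernel SVM, and Gaussian naive Bayes.
#' Selector-capable entries are the sparse/stepwise/boosting/tree-importance
#' families.
#'
#' @return data frame with columns `name`, `family`, `selector`,
#'   `classifier`, `engine`, `note`.
#' @export
default_algorithm_registry <- function() {
  reg <- rbind(
    c("lasso",            "LASSO",       TRUE,  TRUE,  "glmnet",  "alpha=1"),
    c("ridge",            "Ridge",       FALSE, TRUE,  "glmnet",  "alpha=0"),
    c("enet",             "ElasticNet",  TRUE,  TRUE,  "glmnet",  "alpha=0.5"),
    c("stepglm_backward", "Stepglm",     TRUE,  TRUE,  "stats",   "AIC backward"),
    c("stepglm_forward",  "Stepglm",     TRUE,  TRUE,  "stats",   "AIC forward"),
    c("stepglm_both",     "Stepglm",     TRUE,  TRUE,  "stats",   "AIC both"),
    c("glmboost",         "GlmBoost",    TRUE,  TRUE,  "lnmeta",  "componentwise L2 boosting"),
    c("lda",              "LDA",         FALSE, TRUE,  "MASS",    ""),
    c("plsglm",           "plsRglm",     FALSE, TRUE,  "mixOmics","2 components + logit"),
    c("rf",               "RSF",         TRUE,  TRUE,  "ranger",  "probability forest; classification analogue of the survival forest for binary outcomes"),
    c("gbm",              "GBM",         FALSE, TRUE,  "xgboost", "shrinkage 0.05, depth 3, subsample 0.8"),
    c("xgboost",          "XGBoost",     FALSE, TRUE,  "xgboost", "defaults, 50 rounds"),
    c("svm",              "SVM",         FALSE, TRUE,  "e1071",   "radial kernel, Platt probabilities"),
    c("naive_bayes",      "NaiveBayes",  FALSE, TRUE,  "e1071",   "Gaussian")
  )
  data.frame(name = reg[, 1], algorithm = reg[, 2],
             selector = as.logical(reg[, 3]),
             classifier = as.logical(reg[, 4]),
             engine = reg[, 5], note = reg[, 6],
             stringsAsFactors = FALSE)
}

#' Enumerate selector x classifier model specifications for a panel
#'
#' Every selector-capable algorithm crossed with every classifier-capable
#' one, plus each classifier alone, in deterministic registry order with no
#' duplicate pairs.
#'
#' @param registry a registry data frame (see
#'   [default_algorithm_registry()]).
#' @param panel a `feature_panel`.
#' @return list of `model_spec` objects: `selector` (or `NA`), `classifier`,
#'   `panel_id`, `genes`.
#' @export
enumerate_combinations <- function(registry, panel) {
  abort_if(nrow(registry) == 0L, "registry is empty")
  stopifnot(inherits(panel, "feature_panel"))
  sels <- registry$name[registry$selector]
  clfs <- registry$name[registry$classifier]
  specs <- list()
  for (s in sels) {
    for (cl in clfs) {
      specs[[length(specs) + 1L]] <-
        structure(list(selector = s, classifier = cl,
                       panel_id = panel$panel_id, genes = panel$genes),
                  class = "model_spec")
    }
  }
  for (cl in clfs) {
    specs[[length(specs) + 1L]] <-
      structure(list(selector = NA_character_, classifier = cl,
                     panel_id = panel$panel_id, genes = panel$genes),
                class = "model_spec")
  }
  specs
}

# ---- model engines ---------------------------------------------------------

# componentwise L2 boosting for linear models: repeatedly fits the single
# best covariate to the current residual and accumulates shrunken
# coefficients; the in-package glmBoost-family engine
cwb_fit <- function(X, y, mstop = 100L, nu = 0.1) {
  Xs <- scale(X)
  ctr <- attr(Xs, "scaled:center"); scl <- attr(Xs, "scaled:scale")
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  beta <- numeric(ncol(X))
  f <- rep(mean(y), length(y))
  for (m in seq_len(mstop)) {
    r <- y - f
    bj <- crossprod(Xs, r) / nrow(X) # per-covariate LS slope (unit variance)
    j <- which.max(abs(bj))
    beta[j] <- beta[j] + nu * bj[j]
    f <- f + nu * bj[j] * Xs[, j]
  }
  list(beta = beta, center = ctr, scale = scl, intercept = mean(y),
       features = colnames(X))
}

cwb_predict <- function(fit, X) {
  Xs <- sweep(sweep(X[, fit$features, drop = FALSE], 2L, fit$center, "-"),
              2L, fit$scale, "/")
  drop(fit$intercept + Xs %*% fit$beta)
}

glmnet_foldid <- function(n, nfolds, seed) {
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(nfolds), n))
}

# fit one classifier; returns list(engine, fit, predict(newX) -> scores)
fit_classifier_engine <- function(name, X, y, seed) {
  n <- nrow(X)
  switch(name,
    lasso = , ridge = , enet = {
      alpha <- c(lasso = 1, ridge = 0, enet = 0.5)[[name]]
      cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                              nfolds = 5,
                              foldid = glmnet_foldid(n, 5, seed))
      list(predict = function(newX) {
        drop(stats::predict(cv, newx = newX, s = "lambda.min",
                            type = "link"))
      })
    },
    stepglm_backward = , stepglm_forward = , stepglm_both = {
      direction <- sub("stepglm_", "", name)
      if (direction == "backward") direction <- "backward"
      df <- data.frame(y = y, X, check.names = FALSE)
      full <- stats::glm(y ~ ., data = df, family = stats::binomial())
      null <- stats::glm(y ~ 1, data = df, family = stats::binomial())
      fit <- if (direction == "backward") {
        stats::step(full, direction = "backward", trace = 0)
      } else {
        stats::step(null, direction = direction,
                    scope = list(lower = stats::formula(null),
                                 upper = stats::formula(full)), trace = 0)
      }
      list(predict = function(newX) {
        nd <- data.frame(newX, check.names = FALSE)
        unname(stats::predict(fit, newdata = nd, type = "link"))
      })
    },
    glmboost = {
      fit <- cwb_fit(X, y)
      list(predict = function(newX) cwb_predict(fit, newX))
    },
    lda = {
      fit <- MASS::lda(X, grouping = factor(y, levels = c(0, 1)))
      list(predict = function(newX) {
        unname(stats::predict(fit, newX)$posterior[, "1"])
      })
    },
    plsglm = {
      ncomp <- max(1L, min(2L, ncol(X) - 1L))
      pls <- mixOmics::pls(X, y, ncomp = ncomp, scale = TRUE)
      sc <- pls$variates$X
      gdf <- data.frame(y = y, sc)
      glmfit <- stats::glm(y ~ ., data = gdf, family = stats::binomial())
      list(predict = function(newX) {
        v <- stats::predict(pls, newdata = newX)$variates
        colnames(v) <- colnames(sc)
        unname(stats::predict(glmfit, newdata = data.frame(v),
                              type = "link"))
      })
    },
    rf = {
      fit <- ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                            probability = TRUE, num.trees = 500,
                            seed = as.integer(seed), num.threads = 1L)
      list(predict = function(newX) {
        stats::predict(fit, data = newX,
                       num.threads = 1L)$predictions[, "1"]
      })
    },
    gbm = , xgboost = {
      params <- if (name == "gbm") {
        list(eta = 0.05, max_depth = 3, subsample = 0.8,
             colsample_bytree = 0.8)
      } else {
        list(eta = 0.3, max_depth = 4)
      }
      nrounds <- if (name == "gbm") 100L else 50L
      set.seed(as.integer(seed))
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- xgboost::xgb.train(
        params = c(params, list(objective = "binary:logistic",
                                nthread = 1L, seed = as.integer(seed))),
        data = dtrain, nrounds = nrounds, verbose = 0)
      list(predict = function(newX) {
        stats::predict(fit, xgboost::xgb.DMatrix(newX))
      })
    },
    svm = {
      set.seed(as.integer(seed))
      fit <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                        probability = TRUE)
      list(predict = function(newX) {
        pr <- stats::predict(fit, newX, probability = TRUE)
        unname(attr(pr, "probabilities")[, "1"])
      })
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(X, factor(y, levels = c(0, 1)))
      list(predict = function(newX) {
        unname(stats::predict(fit, newX, type = "raw")[, "1"])
      })
    },
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE)
  )
}

# run one selector; returns a character vector of chosen genes
run_selector <- function(name, X, y, seed) {
  switch(name,
    lasso = , enet = {
      alpha <- if (name == "lasso") 1 else 0.5
      cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                              nfolds = 5,
                              foldid = glmnet_foldid(nrow(X), 5, seed))
      cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
      names(cf)[cf != 0]
    },
    stepglm_backward = , stepglm_forward = , stepglm_both = {
      direction <- sub("stepglm_", "", name)
      df <- data.frame(y = y, X, check.names = FALSE)
      full <- stats::glm(y ~ ., data = df, family = stats::binomial())
      null <- stats::glm(y ~ 1, data = df, family = stats::binomial())
      fit <- if (direction == "backward") {
        stats::step(full, direction = "backward", trace = 0)
      } else {
        stats::step(null, direction = direction,
                    scope = list(lower = stats::formula(null),
                                 upper = stats::formula(full)), trace = 0)
      }
      keep <- attr(stats::terms(fit), "term.labels")
      gsub("^`|`$", "", keep)
    },
    glmboost = {
      # early stopping is the boosting family's selection mechanism
      fit <- cwb_fit(X, y, mstop = 30L)
      fit$features[fit$beta != 0]
    },
    rf = {
      fit <- ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                            importance = "impurity", num.trees = 500,
                            seed = as.integer(seed), num.threads = 1L)
      imp <- fit$variable.importance
      names(imp)[imp > mean(imp)]
    },
    stop(sprintf("unknown selector '%s'", name), call. = FALSE)
  )
}

#' Fit one selector x classifier combination and score it on every cohort
#'
#' The selector (if any) is fit on the pooled training samples and chooses a
#' gene subset (an empty selection falls back to the full panel with a
#' warning); the classifier is fit on that subset; each cohort in
#' `train` and `evaluate` is scored by the concordance index of the
#' predicted scores against the labels. A classifier failure on degenerate
#' input is reported in the result and the pipeline continues.
#'
#' @param spec a `model_spec` from [enumerate_combinations()].
#' @param train,evaluate lists of harmonized `bulk_cohort` objects.
#' @param seed integer seed for this fit.
#' @return a `model_result`: `spec`, `selected_genes`, `per_cohort_cindex`,
#'   `mean_cindex` (over all cohorts), `mean_validation_cindex` (over
#'   `evaluate`), `error` (NULL or condition message).
#' @export
fit_and_score <- function(spec, train, evaluate, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  abort_if(length(spec$genes) == 0L, "panel is unusable (no genes)")
  genes <- spec$genes
  for (co in c(train, evaluate)) {
    abort_if(!all(genes %in% colnames(co$expression)),
             sprintf("panel genes missing from cohort %s", co$cohort_id))
  }
  Xtr <- do.call(rbind, lapply(train, function(co) {
    co$expression[, genes, drop = FALSE]
  }))
  ytr <- unlist(lapply(train, function(co) co$labels))

  result <- tryCatch({
    selected <- genes
    if (!is.na(spec$selector)) {
      selected <- run_selector(spec$selector, Xtr, ytr,
                               derive_seed(seed, 1L))
      selected <- intersect(genes, selected) # keep panel order
      if (length(selected) == 0L) {
        warning(sprintf("%s selected no genes; falling back to full panel",
                        spec$selector), call. = FALSE)
        selected <- genes
      }
    }
    eng <- fit_classifier_engine(spec$classifier,
                                 Xtr[, selected, drop = FALSE], ytr,
                                 derive_seed(seed, 2L))
    all_cohorts <- c(train, evaluate)
    ci <- vapply(all_cohorts, function(co) {
      sc <- eng$predict(co$expression[, selected, drop = FALSE])
      concordance_index(sc, co$labels)
    }, numeric(1))
    names(ci) <- vapply(all_cohorts, function(co) co$cohort_id, character(1))
    val_ids <- vapply(evaluate, function(co) co$cohort_id, character(1))
    list(selected_genes = selected, per_cohort_cindex = ci,
         mean_cindex = mean(ci),
         mean_validation_cindex = mean(ci[val_ids]), error = NULL)
  }, error = function(e) {
    list(selected_genes = character(0),
         per_cohort_cindex = stats::setNames(numeric(0), character(0)),
         mean_cindex = NA_real_, mean_validation_cindex = NA_real_,
         error = conditionMessage(e))
  })
  structure(c(list(spec = spec), result), class = "model_result")
}

#' Rank model results into a leaderboard
#'
#' Rows sorted by mean validation C-index (descending), ties broken by the
#' all-cohort mean then the model name. An optional floor drops rows below a
#' minimum validation C-index, with the dropped count recorded in the
#' `"n_dropped"` attribute.
#'
#' @param results list of `model_result` objects.
#' @param min_cindex optional C-index floor (default `NULL`: keep all).
#' @return a data frame with model, panel, per-cohort C-index columns and
#'   the two means.
#' @export
build_leaderboard <- function(results, min_cindex = NULL) {
  rows <- lapply(results, function(r) {
    nm <- if (is.na(r$spec$selector)) r$spec$classifier else
      paste(r$spec$selector, r$spec$classifier, sep = "+")
    base <- data.frame(model = nm, panel = r$spec$panel_id,
                       n_selected = length(r$selected_genes),
                       mean_cindex = r$mean_cindex,
                       mean_validation_cindex = r$mean_validation_cindex,
                       stringsAsFactors = FALSE)
    for (cid in names(r$per_cohort_cindex)) {
      base[[paste0("cindex_", cid)]] <- r$per_cohort_cindex[[cid]]
    }
    base
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    r[setdiff(all_cols, names(r))] <- NA_real_
    r[all_cols]
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$mean_validation_cindex, -tab$mean_cindex,
                   tab$model), , drop = FALSE]
  rownames(tab) <- NULL
  n_dropped <- 0L
  if (!is.null(min_cindex)) {
    keep <- !is.na(tab$mean_validation_cindex) &
      tab$mean_validation_cindex >= min_cindex
    n_dropped <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "n_dropped") <- n_dropped
  tab
}
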