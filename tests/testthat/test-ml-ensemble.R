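test_that("concordance index matches canonical cases and the pair oracle", {
  expect_equal(concordance_index(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(concordance_index(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(concordance_index(c(0.7, 0.7, 0.1), c(1, 0, 0)), 0.75)
  expect_equal(concordance_index(rep(0.5, 6), rep(0:1, 3)), 0.5)
  expect_error(concordance_index(1:3, c(1, 1, 1)), "both classes")

  set.seed(123)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties likely
    expect_identical(concordance_index(scores, labels),
                     cindex_bruteforce(scores, labels))
  }
})

test_that("score negation reflects the concordance index", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(6:25, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- rnorm(n) # ties a.s. absent
    expect_equal(concordance_index(-scores, labels),
                 1 - concordance_index(scores, labels), tolerance = 1e-12)
  }
})

test_that("harmonization restricts to shared genes and standardizes per cohort", {
  mk <- function(id, genes, n = 10, seed = 1) {
    set.seed(seed)
    e <- matrix(rnorm(n * length(genes)), n, length(genes),
                dimnames = list(sprintf("%s_s%d", id, 1:n), genes))
    structure(list(cohort_id = id, expression = e,
                   labels = rep(0:1, n / 2), gfr = rnorm(n, 90),
                   stage = factor(rep(NA, n), levels = c("II", "III", "IV")),
                   role = "train", truth = NULL), class = "bulk_cohort")
  }
  co <- harmonize_cohorts(list(mk("a", c("a", "b", "c")),
                               mk("b", c("b", "c", "d"), seed = 2)))
  expect_equal(colnames(co[[1]]$expression), c("b", "c"))
  for (x in co) {
    expect_true(all(abs(colMeans(x$expression)) < 1e-9))
    expect_true(all(abs(apply(x$expression, 2, stats::sd) - 1) < 1e-9))
  }

  solo <- mk("z", c("u", "v"))
  solo$expression <- scale(solo$expression)
  out <- harmonize_cohorts(list(solo))[[1]]
  expect_equal(unclass(out$expression), unclass(solo$expression),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(harmonize_cohorts(list(mk("a", "x"), mk("b", "y"))),
               "intersection")
})

test_that("panel intersection keeps meta-program order and flags empties", {
  mp <- structure(list(mp_id = "MP1",
                       member_programs = "p1",
                       top_genes = sprintf("g%d", 1:5),
                       mean_internal_correlation = 1),
                  class = "meta_program")
  panel <- intersect_panel(mp, c("g2", "g4", "g9"), set_name = "S")
  expect_equal(panel$genes, c("g2", "g4"))
  expect_true(panel$usable)
  expect_equal(panel$panel_id, "MP1xS")

  empty <- intersect_panel(mp, c("x1", "x2"))
  expect_false(empty$usable)
  expect_length(empty$genes, 0)

  full <- intersect_panel(mp, sprintf("g%d", 1:50))
  expect_equal(full$genes, mp$top_genes)
})

test_that("combination enumeration is complete, unique, and registry-faithful", {
  reg <- default_algorithm_registry()
  expect_equal(length(unique(reg$algorithm)), 12)
  expect_equal(sum(reg$selector), 7)

  panel <- structure(list(panel_id = "P", genes = c("g1", "g2"),
                          provenance = list(), usable = TRUE),
                     class = "feature_panel")
  small <- reg[reg$name %in% c("lasso", "glmboost", "lda", "naive_bayes",
                               "rf"), ]
  # 3 selectors (lasso, glmboost, rf) x 5 classifiers + 5 solo = 20
  specs <- enumerate_combinations(small, panel)
  expect_length(specs, 3 * 5 + 5)
  keys <- vapply(specs, function(s) paste(s$selector, s$classifier),
                 character(1))
  expect_equal(anyDuplicated(keys), 0)

  two_three <- reg[reg$name %in% c("lasso", "enet", "lda", "svm",
                                   "naive_bayes"), ]
  two_three$selector[two_three$name %in% c("lda", "svm", "naive_bayes")] <- FALSE
  two_three$classifier[two_three$name %in% c("lasso", "enet")] <- FALSE
  expect_length(enumerate_combinations(two_three, panel), 2 * 3 + 3)
})

test_that("every registry classifier fits and scores planted-signal cohorts", {
  setup <- planted_cohort_setup(delta = 1.5, samples_per_arm = 30, seed = 1)
  panel_genes <- setup$params$signal_genes
  reg <- default_algorithm_registry()
  for (clf in reg$name[reg$classifier]) {
    spec <- structure(list(selector = NA_character_, classifier = clf,
                           panel_id = "sig", genes = panel_genes),
                      class = "model_spec")
    res <- fit_and_score(spec, setup$train, setup$validation, seed = 3)
    expect_null(res$error, info = clf)
    expect_true(all(res$per_cohort_cindex >= 0 &
                      res$per_cohort_cindex <= 1), info = clf)
    expect_gt(res$mean_validation_cindex, 0.7)
  }
})

test_that("selectors recover informative genes on planted signal", {
  setup <- planted_cohort_setup(delta = 1.5, samples_per_arm = 30, seed = 2)
  panel_genes <- c(setup$params$signal_genes[1:10],
                   sprintf("g%04d", 101:110)) # 10 signal + 10 noise genes
  reg <- default_algorithm_registry()
  for (sel in reg$name[reg$selector]) {
    spec <- structure(list(selector = sel, classifier = "naive_bayes",
                           panel_id = "mix", genes = panel_genes),
                      class = "model_spec")
    res <- fit_and_score(spec, setup$train, setup$validation, seed = 4)
    expect_null(res$error, info = sel)
    # selected set is enriched for true signal genes
    frac_signal <- mean(res$selected_genes %in%
                          setup$params$signal_genes)
    expect_gt(frac_signal, 0.5)
  }
})

test_that("a perfectly separating gene yields C-index 1 on that cohort", {
  n <- 20
  e <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(sprintf("s%d", 1:n), c("sep", "n1", "n2")))
  labels <- rep(c(0L, 1L), each = n / 2)
  e[, "sep"] <- labels * 10 + rnorm(n, 0, 0.1)
  co <- structure(list(cohort_id = "perfect", expression = scale(e),
                       labels = labels, gfr = rnorm(n, 90),
                       stage = factor(rep(NA, n),
                                      levels = c("II", "III", "IV")),
                       role = "train", truth = NULL), class = "bulk_cohort")
  spec <- structure(list(selector = NA_character_, classifier = "lda",
                         panel_id = "p", genes = c("sep", "n1", "n2")),
                    class = "model_spec")
  res <- fit_and_score(spec, list(co), list(), seed = 1)
  expect_equal(unname(res$per_cohort_cindex["perfect"]), 1.0)
})

test_that("the leaderboard sorts, floors, and stays deterministic", {
  fake <- function(name, val, all) {
    structure(list(spec = structure(list(selector = NA_character_,
                                         classifier = name,
                                         panel_id = "P", genes = "g"),
                                    class = "model_spec"),
                   selected_genes = "g",
                   per_cohort_cindex = c(c1 = all),
                   mean_cindex = all, mean_validation_cindex = val,
                   error = NULL),
              class = "model_result")
  }
  results <- list(fake("a", 0.55, 0.6), fake("b", 0.7, 0.7),
                  fake("c", 0.65, 0.6))
  tab <- build_leaderboard(results)
  expect_equal(tab$model, c("b", "c", "a"))
  expect_equal(attr(tab, "n_dropped"), 0L)

  floored <- build_leaderboard(results, min_cindex = 0.6)
  expect_equal(nrow(floored), 2)
  expect_equal(attr(floored, "n_dropped"), 1L)

  one <- build_leaderboard(results[2])
  expect_equal(nrow(one), 1)

  # determinism: identical inputs give byte-identical serialized tables
  t1 <- build_leaderboard(results)
  t2 <- build_leaderboard(results)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
})
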