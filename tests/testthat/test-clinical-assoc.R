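test_that("case/control tests detect planted shifts and respect the null", {
  p <- bulk_sim_params(n_cohorts = 1, samples_per_arm = 30, delta = 1.5,
                       seed = 1)
  co <- generate_bulk_cohorts(p)[[1]]
  res <- case_control_test(co, p$signal_genes)
  expect_true(all(res$p_adj < 0.05))
  expect_true(all(res$direction == "up"))

  # type-I calibration on 1000 null genes
  pn <- bulk_sim_params(n_cohorts = 1, samples_per_arm = 50, n_genes = 1000,
                        signal_genes = character(0), delta = 0,
                        gfr_beta = 0, stage_beta = 0, seed = 2)
  con <- generate_bulk_cohorts(pn)[[1]]
  null_res <- case_control_test(con, colnames(con$expression))
  rate <- mean(null_res$p_raw < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("constant genes and identical arms degrade gracefully", {
  p <- bulk_sim_params(n_cohorts = 1, samples_per_arm = 5, n_genes = 10,
                       signal_genes = character(0), seed = 3)
  co <- generate_bulk_cohorts(p)[[1]]
  co$expression[, "g0001"] <- 1
  expect_warning(res <- case_control_test(co, "g0001"), "constant")
  expect_equal(res$p_raw, 1)
  expect_equal(res$direction, "none")

  # identical values in both arms (non-constant overall)
  co$expression[, "g0002"] <- rep(c(1, 2, 3, 4, 5), 2)
  res2 <- case_control_test(co, "g0002")
  expect_equal(res2$direction, "none")
})

test_that("clinical correlation handles exact, planted, and missing cases", {
  x <- c(1.2, 3.4, 2.2, 5.1, 0.3, 4.4)
  expect_equal(correlate_clinical(x, x, "pearson")$r, 1)
  expect_equal(correlate_clinical(x, -x, "spearman")$r, -1)

  p <- bulk_sim_params(n_cohorts = 1, samples_per_arm = 50, delta = 1.5,
                       gfr_beta = 1, seed = 3)
  co <- generate_bulk_cohorts(p)[[1]]
  ct <- correlate_clinical(co$expression[, p$signal_genes[1]], co$gfr)
  expect_lt(ct$r, 0)
  expect_lt(ct$p, 0.05)

  gfr_miss <- co$gfr
  gfr_miss[1:5] <- NA
  ct2 <- correlate_clinical(co$expression[, p$signal_genes[1]], gfr_miss)
  expect_equal(attr(ct2, "n_dropped"), 5)
  expect_equal(ct2$n, 95)

  expect_error(correlate_clinical(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate_clinical(1:3, 1:3), "paired")
})

test_that("stage comparisons recover a planted ordinal trend", {
  p <- bulk_sim_params(n_cohorts = 1, samples_per_arm = 90, delta = 1.5,
                       stage_beta = 1.5, seed = 4)
  co <- generate_bulk_cohorts(p)[[1]]
  st <- compare_stages(co$expression[, p$signal_genes[1]], co$stage)
  expect_gt(st$trend$statistic, 0)
  expect_lt(st$pairwise$p_adj[st$pairwise$pair == "IV vs II"], 0.05)

  # shuffled stage labels kill the trend
  set.seed(9)
  taus <- replicate(20, {
    compare_stages(co$expression[, p$signal_genes[1]],
                   sample(co$stage))$trend$statistic
  })
  expect_lt(stats::median(abs(taus)), abs(st$trend$statistic))
  expect_true(any(taus > 0) && any(taus < 0))

  # identical distributions in two stages
  expr <- rep(c(1.3, 2.1, 0.7, 1.9, 1.1), 2)
  stage <- rep(c("II", "III"), each = 5)
  st2 <- compare_stages(expr, stage)
  expect_gt(st2$pairwise$p_raw[1], 0.9)

  expect_warning(compare_stages(rnorm(10),
                                c(rep("II", 5), rep("III", 3),
                                  rep("IV", 2))),
                 "excluded")
})

test_that("hypergeometric ORA matches the exact enumeration oracle", {
  universe <- sprintf("u%02d", 1:10)
  set5 <- universe[1:5]
  query <- universe[1:3]
  res <- ora_hypergeometric(query, list(S = set5), universe)
  expect_equal(res$p_raw, 10 / 120, tolerance = 1e-12)
  expect_equal(res$overlap, 3)

  # random small universes against brute-force subset enumeration
  set.seed(21)
  for (i in 1:25) {
    n_u <- sample(6:15, 1)
    uni <- sprintf("x%02d", seq_len(n_u))
    s <- sample(uni, sample(2:(n_u - 1), 1))
    q <- sample(uni, sample(2:5, 1))
    got <- ora_hypergeometric(q, list(S = s), uni)$p_raw
    expect_equal(got, ora_bruteforce(q, s, uni), tolerance = 1e-12)
  }

  # zero overlap is never significant
  res0 <- ora_hypergeometric(universe[6:7], list(S = universe[1:3]), universe)
  expect_equal(res0$p_raw, 1)

  # growing the overlap never increases the tail probability
  p_prev <- 1
  for (j in 1:5) {
    pj <- ora_hypergeometric(universe[seq_len(j)], list(S = set5),
                             universe)$p_raw
    expect_lte(pj, p_prev + 1e-12)
    p_prev <- pj
  }

  expect_error(ora_hypergeometric("zz", list(S = set5), universe), "subset")
})

test_that("exclusive intersection counts partition the union", {
  out <- set_intersection_counts(list(A = c("1", "2", "3"),
                                      B = c("2", "3", "4"),
                                      C = "3"))
  get <- function(cmb) out$count[out$combination == cmb]
  expect_equal(get("A"), 1)
  expect_equal(get("B"), 1)
  expect_equal(get("A&B"), 1)
  expect_equal(get("A&B&C"), 1)
  expect_equal(sum(out$count), 4)

  disj <- set_intersection_counts(list(A = c("a", "b"), B = c("c")))
  expect_equal(disj$count[disj$combination == "A"], 2)
  expect_equal(disj$count[disj$combination == "A&B"], 0)

  same <- set_intersection_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$count[same$combination == "A&B"], 2)
  expect_equal(sum(same$count), 2)

  # conservation on random families
  set.seed(31)
  for (i in 1:100) {
    n_sets <- sample(2:4, 1)
    fam <- lapply(seq_len(n_sets), function(j) {
      sample(letters, sample(1:10, 1))
    })
    names(fam) <- LETTERS[seq_len(n_sets)]
    tab <- set_intersection_counts(fam)
    expect_equal(sum(tab$count), length(unique(unlist(fam))))
  }
})

test_that("BH adjustment in association outputs matches the reference step-up", {
  set.seed(41)
  p <- bulk_sim_params(n_cohorts = 1, samples_per_arm = 20, n_genes = 50,
                       signal_genes = sprintf("g%04d", 1:5), delta = 1,
                       seed = 6)
  co <- generate_bulk_cohorts(p)[[1]]
  res <- case_control_test(co, colnames(co$expression))
  expect_equal(res$p_adj, stats::p.adjust(res$p_raw, "BH"))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_true(all(res$p_adj <= 1))
})
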