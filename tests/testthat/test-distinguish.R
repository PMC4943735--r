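test_that("dataset and config constructors enforce their invariants", {
  m <- matrix(runif(40), 10, 4)
  expect_error(signature_dataset(m, rep("a", 9)), "one entry per")
  m2 <- m; m2[1, 1] <- NA
  expect_error(signature_dataset(m2, rep(c("a", "b"), 5)), "missing")
  expect_error(classifier_config(C = 0), "C must be")
  expect_error(classifier_config(tolerance = -1), "tolerance")
  ds1 <- signature_dataset(m, rep("a", 10))
  expect_error(loo_success_rate(ds1), "single class")
  ds3 <- signature_dataset(m, rep(c("a", "b", "c"), length.out = 10))
  expect_error(loo_success_rate(ds3), "pairwise")
  ds_small <- signature_dataset(m[1:3, ], c("a", "a", "b"))
  expect_error(loo_success_rate(ds_small), ">= 2 members")
})

test_that("perfectly separated classes give LOO success 1 and an exact rate", {
  ds <- separated_dataset(5, 10)
  res <- loo_success_rate(ds)
  expect_equal(res$success_rate, 1.0)
  expect_equal(res$predicted, ds$labels)
  # rate * n is always an integer
  expect_equal(res$success_rate * res$n, round(res$success_rate * res$n))
})

test_that("label-independent signatures give near-chance mean LOO success", {
  rates <- vapply(1:50, function(s) {
    ds <- null_signature_dataset(n = 20, T = 10, seed = 100 + s)
    loo_success_rate(ds)$success_rate
  }, numeric(1))
  expect_gt(mean(rates), 0.35)
  expect_lt(mean(rates), 0.65)
  expect_true(all(rates * 20 == round(rates * 20)))
})

test_that("swapping the two class names leaves rate and p unchanged", {
  ds <- null_signature_dataset(n = 12, T = 6, seed = 5)
  swapped <- signature_dataset(ds$matrix,
                               ifelse(ds$labels == "a", "b", "a"))
  r1 <- loo_success_rate(ds)
  r2 <- loo_success_rate(swapped)
  expect_equal(r1$success_rate, r2$success_rate)
  p1 <- permutation_p_value(ds, n_permutations = 99, seed = 7)
  p2 <- permutation_p_value(swapped, n_permutations = 99, seed = 7)
  expect_equal(p1$p_value, p2$p_value)
})

test_that("permutation p is reproducible, bounded, and significant for separated classes", {
  # 6 + 6 keeps the chance of drawing a cluster-aligned permutation (the
  # only labelings that can tie the observed rate of 1) near zero
  ds <- separated_dataset(6, 10)
  res <- permutation_p_value(ds, n_permutations = 199, seed = 11)
  expect_equal(res$observed_rate, 1.0)
  expect_lte(res$p_value, 0.01)
  expect_gte(res$p_value, 1 / 200)
  expect_equal(length(res$null_rates), 199L)
  res2 <- permutation_p_value(ds, n_permutations = 199, seed = 11)
  expect_identical(res$null_rates, res2$null_rates)
  res3 <- permutation_p_value(ds, n_permutations = 199, seed = 12)
  expect_false(identical(res$null_rates, res3$null_rates))
  expect_error(permutation_p_value(ds, n_permutations = 50), ">= 99")
})

test_that("small-sample permutation nulls have the documented heavy upper tail", {
  # with n = 5 + 5 in 10 dimensions, label permutations can reach perfect
  # LOO by chance, so a perfect observed rate need not be significant —
  # the reason analyses report n per class alongside p
  ds <- separated_dataset(5, 10)
  res <- permutation_p_value(ds, n_permutations = 199, seed = 11)
  expect_equal(res$observed_rate, 1.0)
  expect_gte(sum(res$null_rates == 1), 1)
})

test_that("p-values are calibrated (stochastically >= uniform) under the null", {
  n_datasets <- 40
  pvals <- vapply(seq_len(n_datasets), function(s) {
    ds <- null_signature_dataset(n = 10, T = 8, seed = 300 + s)
    permutation_p_value(ds, n_permutations = 99, seed = 400 + s)$p_value
  }, numeric(1))
  expect_true(all(pvals >= 1 / 100 & pvals <= 1))
  # exact-binomial 99% upper bound on the number of p < 0.05 at nominal 5%
  expect_lte(sum(pvals < 0.05), qbinom(0.995, n_datasets, 0.05))
})

test_that("the pairwise driver covers pairs, validates, and applies Holm flags", {
  # 8 per class in 6 dimensions: enough samples that chance permutations
  # cannot reach perfect LOO on the separated pairs
  set.seed(21)
  m <- rbind(matrix(rnorm(48, 0), 8), matrix(rnorm(48, 4), 8),
             matrix(rnorm(48, 0), 8))
  ds <- signature_dataset(pmin(pmax(m, -6), 6) / 6 + 1,
                          rep(c("p1", "p2", "p3"), each = 8))
  tab <- pairwise_distinguishability(ds, n_permutations = 99, seed = 3)
  expect_equal(nrow(tab), 3L)
  expect_setequal(paste(tab$class1, tab$class2),
                  c("p1 p2", "p1 p3", "p2 p3"))
  # p1 and p3 are drawn from the same distribution; p2 is far away
  far <- tab$p_value[paste(tab$class1, tab$class2) != "p1 p3"]
  near <- tab$p_value[paste(tab$class1, tab$class2) == "p1 p3"]
  expect_true(all(far <= 0.05))
  expect_gt(near, 0.05)
  sub <- pairwise_distinguishability(ds, n_permutations = 99, seed = 3,
                                     pairs = list(c("p1", "p2")))
  expect_equal(nrow(sub), 1L)
  expect_error(pairwise_distinguishability(ds, pairs = list(c("p1", "zz"))),
               "unknown class")
})

test_that("Holm flags reproduce the hand-computed step-down sequence", {
  # ordered p (0.001, 0.02, 0.04) vs thresholds 0.05/3, 0.05/2, 0.05/1:
  # every comparison passes, so the adjusted values 0.003, 0.04, 0.04 are
  # all significant at the 0.05 family-wise level
  expect_equal(holm_flags(c(0.001, 0.02, 0.04), alpha = 0.05),
               c(TRUE, TRUE, TRUE))
  expect_equal(stats::p.adjust(c(0.001, 0.02, 0.04), "holm"),
               c(0.003, 0.04, 0.04))
  # a sequence where the step-down stops early
  expect_equal(holm_flags(c(0.001, 0.03, 0.04), alpha = 0.05),
               c(TRUE, FALSE, FALSE))
})

test_that("unknowns identical to one training class are fully assigned to it", {
  ds <- separated_dataset(5, 10)
  unknowns <- ds$matrix[ds$labels == "hi", ]
  res <- assign_unknowns(ds, unknowns, n_permutations = 99, seed = 2)
  expect_equal(unname(res$fractions["hi"]), 1.0)
  expect_equal(unname(res$fractions["lo"]), 0.0)
  expect_equal(sum(res$fractions), 1.0)
  expect_named(res$group_separability, c("hi", "lo"))
  # identical points cannot be separated from their own class
  expect_gt(res$group_separability$hi$p_value, 0.05)
  expect_error(assign_unknowns(ds, unknowns[, 1:3]), "same number of columns")
})

test_that("unknowns drawn from a training class's distribution mostly rejoin it", {
  hits <- 0; seps <- 0; n_rep <- 10
  for (r in seq_len(n_rep)) {
    ds <- pattsig:::with_seed(500 + r, {
      a <- matrix(runif(10 * 8), 10)            # class a: uniform(0,1)
      b <- matrix(runif(10 * 8, 1.2, 2.2), 10)  # class b: shifted
      signature_dataset(rbind(a, b), rep(c("a", "b"), each = 10))
    })
    unknowns <- pattsig:::with_seed(600 + r, matrix(runif(10 * 8), 10))
    res <- assign_unknowns(ds, unknowns, n_permutations = 99, seed = 700 + r)
    if (res$fractions["a"] > 0.5) hits <- hits + 1
    if (res$group_separability$a$p_value > 0.05) seps <- seps + 1
  }
  expect_gte(hits, 8)
  expect_gte(seps, 8)
})
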