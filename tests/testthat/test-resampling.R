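# Resampling inference: exceedance test, permutation ANOVA, rank-sum test,
# and bootstrap effect sizes, checked against exact enumeration oracles.

test_that("exceedance test behaves under the null and the headline contrast", {
  # target indistinguishable from the pool: about half the resamples reach it
  null_res <- exceedance_test(calls_of(10, 20), calls_of(1000, 2000),
                              n_resamples = 4000, seed = 5)
  expect_gt(null_res$exceedance_count / 4000, 0.4)
  expect_lt(null_res$exceedance_count / 4000, 0.8)

  # 17/20 single-cell vs 120/2000 whole-culture: no resample reaches 85%
  res <- exceedance_test(calls_of(17, 20), calls_of(120, 2000),
                         n_resamples = 5000, seed = 1)
  expect_equal(res$exceedance_count, 0)
  expect_equal(res$p_value, 1 / 5001)
  expect_error(exceedance_test(calls_of(1, 2), calls_of(1, 2),
                               n_resamples = 10), "100")
})

test_that("exceedance resampling matches the exact binomial distribution", {
  # with-replacement resampling of k calls from a pool is Binomial(k, p)/k
  for (case in list(list(t = calls_of(2, 2), r = calls_of(1, 2)),
                    list(t = calls_of(1, 3), r = calls_of(3, 4)))) {
    res <- exceedance_test(case$t, case$r, n_resamples = 20000, seed = 3)
    exact <- exact_exceedance_prob(c(case$t, case$r), length(case$t),
                                   mean(case$t))
    expect_equal(res$exceedance_count / res$n_resamples, exact,
                 tolerance = 0.05)
  }
})

test_that("permutation ANOVA matches exhaustive enumeration on tiny groups", {
  groups <- list(c(1.2, 3.4), c(2.2, 5.1), c(9.7, 8.3)) # 6 distinct values
  res <- permutation_anova(groups, n_perm = 5000, seed = 11)
  exact <- exact_anova_p(groups)
  expect_equal(res$p_value, exact, tolerance = 0.03)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("separated groups reach the minimum attainable p-value", {
  set.seed(19)
  a <- rnorm(50)
  b <- rnorm(50) + 5 * sd(c(a, rnorm(50)))
  res <- permutation_anova(list(a, b), n_perm = 2000, seed = 4)
  expect_equal(res$p_value, 1 / 2001)
  expect_error(permutation_anova(list(1:5, 3)), "at least 2")
})

test_that("permutation ANOVA holds its type-I error rate", {
  # null: three groups from one distribution; nominal alpha = 0.05
  set.seed(500)
  n_rep <- 200
  rejections <- vapply(seq_len(n_rep), function(i) {
    g <- list(rnorm(15), rnorm(15), rnorm(15))
    permutation_anova(g, n_perm = 199, seed = i)$p_value <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("rank-sum test is exact on small samples", {
  # identical constant samples: every assignment ties, p = 1
  expect_equal(rank_sum_test(rep(1, 4), rep(1, 4))$p_value, 1)
  # enumeration of C(4,2) assignments: {1,2} vs {3,4} gives 2/6
  expect_equal(rank_sum_test(c(1, 2), c(3, 4))$p_value, 2 / 6)
  # agrees with the independent implementation in stats:: on tie-free data
  set.seed(23)
  for (i in 1:5) {
    a <- rnorm(6)
    b <- rnorm(7) + 0.5
    expect_equal(rank_sum_test(a, b)$p_value,
                 stats::wilcox.test(a, b)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("rank-sum large-sample branch approximates the exact test", {
  set.seed(29)
  a <- rnorm(30)
  b <- rnorm(30) + 0.8
  got <- rank_sum_test(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_match(got$method, "normal approximation")
  # complete separation at n = 30 is overwhelming
  expect_lt(rank_sum_test(rnorm(30), rnorm(30) + 100)$p_value, 1e-6)
  # ties handled via mid-ranks
  set.seed(31)
  at <- sample(1:4, 40, replace = TRUE)
  bt <- sample(2:5, 40, replace = TRUE)
  expect_equal(rank_sum_test(at, bt)$p_value,
               stats::wilcox.test(at, bt, exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("effect-size difference reproduces the 79 +/- 8 point contrast", {
  res <- effect_size_difference(calls_of(17, 20), calls_of(120, 2000),
                                n_boot = 5000, seed = 13)
  expect_equal(res$difference_pp, 79, tolerance = 1e-9)
  closed <- 100 * sqrt(0.85 * 0.15 / 20 + 0.06 * 0.94 / 2000)
  expect_equal(res$se_pp, closed, tolerance = 0.1)

  # identical groups: difference 0, se ~ sqrt(2) x binomial se
  same <- effect_size_difference(calls_of(10, 40), calls_of(10, 40),
                                 n_boot = 5000, seed = 2)
  expect_equal(same$difference_pp, 0)
  expect_equal(same$se_pp, 100 * sqrt(2 * 0.25 * 0.75 / 40),
               tolerance = 0.1)

  # degenerate all-negative groups
  zero <- effect_size_difference(calls_of(0, 20), calls_of(0, 2000),
                                 n_boot = 500, seed = 3)
  expect_equal(zero$difference_pp, 0)
  expect_equal(zero$se_pp, 0)
})

test_that("median-ratio effect is scale-equivariant and recovers truth", {
  set.seed(37)
  a <- rlnorm(100, 0, 0.3)
  same <- median_ratio_effect(a, a, n_boot = 500, seed = 1)
  expect_equal(same$percent_change, 0)

  scaled <- median_ratio_effect(a, 0.9 * a, n_boot = 500, seed = 1)
  expect_equal(scaled$percent_change, -10, tolerance = 1e-9)

  # simulation oracle: true median ratio 0.94 -> about -6% with tight se
  set.seed(38)
  ga <- rlnorm(500, log(1), 0.2)
  gb <- rlnorm(500, log(0.94), 0.2)
  res <- median_ratio_effect(ga, gb, n_boot = 2000, seed = 7)
  expect_lt(abs(res$percent_change - (-6)), 3 * res$se)
  expect_error(median_ratio_effect(c(0, 0, 0, 0, 0), ga), "zero")
})

test_that("resampling operations are seed-deterministic with valid p-values", {
  a <- calls_of(8, 20)
  b <- calls_of(30, 100)
  r1 <- exceedance_test(a, b, n_resamples = 1000, seed = 99)
  r2 <- exceedance_test(a, b, n_resamples = 1000, seed = 99)
  expect_identical(r1, r2)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  set.seed(4)
  g <- list(rnorm(10), rnorm(10))
  p1 <- permutation_anova(g, n_perm = 500, seed = 3)
  p2 <- permutation_anova(g, n_perm = 500, seed = 3)
  expect_identical(p1, p2)
})
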