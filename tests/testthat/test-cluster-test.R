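test_that("gap normalisation matches hand arithmetic and flags bad clusters", {
  expect_equal(normalize_gaps(c(0, 5, 10)), c(0.5, 0.5))
  expect_equal(normalize_gaps(c(0, 2, 10)), c(0.2, 0.8))
  expect_equal(normalize_gaps(c(0, 1, 2, 3)), rep(1/3, 3))
  expect_equal(sum(normalize_gaps(c(3.2, 9.7, 11.1, 40))), 1)
  expect_error(normalize_gaps(c(1, 2)), "at least 3")
  expect_error(normalize_gaps(c(2, 2, 2)), "degenerate")
  expect_warning(normalize_gaps(c(0, 1, 1, 3)), "zero-width")
})

test_that("the statistic S reproduces hand evaluations", {
  expect_equal(cluster_statistic(c(0.5, 0.5)), 0)
  expect_equal(cluster_statistic(c(0.2, 0.8)), 2.16)
  expect_equal(cluster_statistic(rep(1/3, 3)), 0)
  # k = 2 hand evaluation: sum((d - 1/3)^2) * 9 * 4 / 2
  g <- c(0.1, 0.3, 0.6)
  expect_equal(cluster_statistic(g), sum((g - 1/3)^2) * 18)
  expect_error(cluster_statistic(c(1)), "k = 0")
  expect_error(cluster_statistic(c(0.3, 0.3)), "sum to 1")
})

test_that("S is invariant to affine rescaling of positions", {
  set.seed(11)
  for (i in 1:20) {
    p <- sort(stats::runif(sample(3:7, 1), 0, 100))
    s1 <- cluster_statistic(normalize_gaps(p))
    s2 <- cluster_statistic(normalize_gaps(3.7 * p - 12))
    expect_equal(s1, s2)
  }
})

test_that("null mean of S_total equals the Dirichlet closed form sum(k + 1)", {
  k <- c(1, 2, 3)
  s0 <- simulate_null_S(k, n_sim = 10000, seed = 101)
  se <- stats::sd(s0) / sqrt(length(s0))
  expect_lt(abs(mean(s0) - sum(k + 1)), 3 * se)
  # single cluster with one internal focus: E[S] = 2
  s1 <- simulate_null_S(1, n_sim = 10000, seed = 102)
  expect_lt(abs(mean(s1) - 2), 3 * stats::sd(s1) / sqrt(length(s1)))
  expect_error(simulate_null_S(c(0, 1)), "k >= 1")
})

test_that("the Monte-Carlo p-value uses the strict smaller-than rule", {
  null_s <- c(1, 2, 3, 4)
  expect_equal(mc_pvalue(0, null_s), 0)
  expect_equal(mc_pvalue(10, null_s), 1)
  expect_equal(mc_pvalue(2.5, null_s), 0.5)
  expect_equal(mc_pvalue(2, null_s), 0.25) # ties are not "smaller"
  expect_equal(mc_pvalue(0, null_s, corrected = TRUE), 1/5)
})

test_that("regularly spaced foci are detected as interfering (power)", {
  set.seed(12)
  rejections <- vapply(1:60, function(i) {
    cl <- lapply(c(2, 2, 3), function(k) {
      inner <- (1:k) / (k + 1) + stats::rnorm(k, 0, 0.02)
      c(0, sort(inner), 1)
    })
    cluster_interference_test(cl, n_sim = 1000,
                              seed = sample.int(1e6, 1))$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rejections), 0.5) # far above the 5% nominal rate
})

test_that("cluster test input handling and summaries are coherent", {
  cl <- list(c(0, 5, 10), c(2, 4.1, 6, 8), c(0, 0.4)) # last untestable
  ct <- cluster_interference_test(cl, n_sim = 500, seed = 9)
  expect_identical(nrow(ct$per_cluster), 2L)
  expect_equal(ct$S_total, sum(ct$per_cluster$statistic))
  expect_true(ct$p_value >= 0 && ct$p_value <= 1)
  expect_error(cluster_interference_test(list(c(0, 1))), "no testable")
  # the cv statistic variant runs on the same machinery
  ct_cv <- cluster_interference_test(cl, n_sim = 500, seed = 9,
                                     statistic = "cv")
  expect_true(is.finite(ct_cv$p_value))
})
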