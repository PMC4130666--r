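test_that("Perkins distance reproduces hand evaluations of the formula", {
  expect_equal(perkins_distance(P = 100, T = 0, NPD = 0), 0)
  expect_equal(perkins_distance(P = 50, T = 50, NPD = 0), 25)
  expect_equal(perkins_distance(P = 0, T = 0, NPD = 100), 300)
  expect_error(perkins_distance(P = 0, T = 0, NPD = 0), "undefined")
})

test_that("Perkins distance without NPDs reduces to 50 T / n", {
  set.seed(4)
  for (i in 1:20) {
    P <- sample(0:500, 1); T <- sample(1:500, 1)
    expect_equal(perkins_distance(P = P, T = T, NPD = 0), 50 * T / (P + T))
  }
})

test_that("expected NPD frequency follows the Papazian closed form", {
  expect_equal(expected_npd(0), 0)
  expect_equal(expected_npd(2/3), 1/6)
  expect_equal(expected_npd(0.2), 0.5 * (0.8 - 0.7^(2/3)))
  grid <- seq(0, 2/3, length.out = 200)
  expect_true(all(diff(expected_npd(grid)) > 0)) # monotone increasing
  expect_error(expected_npd(0.7), "2/3")
  expect_error(expected_npd(-0.1), "2/3")
})

test_that("NPD ratio handles boundary and inconsistent inputs", {
  x <- counts_of(a = 80, b = 20) # T but no NPD in interval 1
  r <- npd_ratio(interval_ptn(x, 1), n_resamples = 200, seed = 1)
  expect_equal(r$value, 0)
  expect_true(r$p_vs_1 >= 0 && r$p_vs_1 <= 1)
  # NPD without any tetratype is inconsistent with the tetrad model
  bad <- list(P = 90, T = 0, NPD = 10, n_total = 100, interval = 1L)
  class(bad) <- "interval_ptn"
  expect_error(npd_ratio(bad), "inconsistent")
})

test_that("interference ratio is exactly 1 when conditional proportions match", {
  # target statuses identical among tetrads with and without adjacent CO
  x <- counts_of(a = 90, b = 10, c = 90, d = 10)
  ir <- interference_ratio(x, target_interval = 1, n_resamples = 500, seed = 2)
  expect_equal(ir$value, 1)
  expect_equal(ir$components$d_with, ir$components$d_without)
  # empty conditional subset is an error
  expect_error(interference_ratio(counts_of(a = 100), 1, n_resamples = 0),
               "undefined IR")
})

test_that("coefficient of coincidence matches direct arithmetic", {
  # f(CO in 1) = 0.2, f(CO in 2) = 0.2, f(both) = 0.02 -> c.o.c. = 0.5
  x <- counts_of(a = 62, b = 18, c = 18, d = 2)
  cc <- coefficient_of_coincidence(x, n_resamples = 500, seed = 3)
  expect_equal(cc$value, 0.5)
  expect_equal(cc$components$f_obs, 0.02)
  expect_equal(cc$components$f_exp, 0.04)
  # no double-CO tetrads at all
  cc0 <- coefficient_of_coincidence(counts_of(a = 80, b = 10, c = 10),
                                    n_resamples = 200, seed = 4)
  expect_equal(cc0$value, 0)
  expect_error(coefficient_of_coincidence(counts_of(a = 90, b = 10)),
               "undefined")
})

test_that("interference statistics shift in the right direction with nu", {
  null_cfg <- sim_config(nu = 1, mean_co_per_bivalent = 2, n_tetrads = 30000,
                         seed = 41)
  strong_cfg <- sim_config(nu = 10, mean_co_per_bivalent = 2, n_tetrads = 30000,
                           seed = 42)
  x1 <- simulate_tetrad_dataset(null_cfg)
  x10 <- simulate_tetrad_dataset(strong_cfg)
  ir1 <- interference_ratio(x1, 1, n_resamples = 1000, seed = 1)
  ir10 <- interference_ratio(x10, 1, n_resamples = 1000, seed = 1)
  expect_lt(ir10$value, 1)
  expect_lt(ir10$value, ir1$value)
  npdr10 <- npd_ratio(interval_ptn(x10, 1), n_resamples = 200, seed = 1)
  expect_lt(npdr10$value, 1)
  cc10 <- coefficient_of_coincidence(x10, n_resamples = 200, seed = 1)
  expect_lt(cc10$value, 1)
})

test_that("comparison against a reference genotype detects an IR difference", {
  mut <- simulate_tetrad_dataset(sim_config(nu = 1, n_tetrads = 20000,
                                            seed = 51))
  wt <- simulate_tetrad_dataset(sim_config(nu = 10, n_tetrads = 20000,
                                           seed = 52))
  ir <- interference_ratio(mut, 1, n_resamples = 2000, seed = 5,
                           reference = wt)
  expect_lt(ir$p_vs_reference, 0.01) # nu = 1 vs nu = 10 differ clearly
  same <- interference_ratio(mut, 1, n_resamples = 2000, seed = 6,
                             reference = mut)
  expect_gt(same$p_vs_reference, 0.05)
})

test_that("bootstrap p-values for IR are approximately uniform under the null", {
  ps <- vapply(1:200, function(i) {
    x <- simulate_tetrad_dataset(sim_config(nu = 1, n_tetrads = 2000,
                                            seed = 1000 + i))
    interference_ratio(x, 1, n_resamples = 400, seed = i)$p_vs_1
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # and the test is not anti-conservative at the 5% level
  expect_lt(mean(ps < 0.05), 0.11)
})

test_that("tetrad_counts validates its input", {
  expect_error(tetrad_counts(1:5), "12")
  expect_error(counts_of(a = -1), "non-negative")
  shuffled <- stats::setNames(c(5L, rep(0L, 11)), sample(letters[1:12]))
  x <- tetrad_counts(shuffled)
  expect_identical(unname(x[[names(shuffled)[1]]]), 5L)
})
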