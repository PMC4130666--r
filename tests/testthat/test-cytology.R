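test_that("minimum chiasma number follows the rod = 1 / ring = 2 rule", {
  expect_identical(mcn(0, 0), 0L)
  expect_identical(mcn(5, 0), 10L)
  expect_identical(mcn(3, 2), 8L)
  expect_identical(mcn(c(0, 5, 3), c(0, 0, 2)), c(0L, 10L, 8L))
  expect_error(mcn(-1, 0), ">= 0")
})

test_that("metaphase summaries and group comparisons behave sensibly", {
  five_rings <- data.frame(n_ring = rep(5L, 5), n_rod = 0L,
                           n_univalent_pairs = 0L)
  s <- metaphase_summary(five_rings)
  expect_equal(s$groups$mean_mcn, 10)
  expect_equal(s$groups$sd_mcn, 0)
  expect_equal(s$groups$mean_bivalents, 5)

  # identical groups: no difference
  g <- simulate_metaphase(30, mean_co_per_arm = 1, seed = 8)
  same <- metaphase_summary(g, g)
  expect_equal(same$groups$mean_mcn[1], same$groups$mean_mcn[2])
  expect_gt(same$p_mcn, 0.99)

  # distinct CO regimes are recovered as significant
  lo <- simulate_metaphase(60, mean_co_per_arm = 0.3, seed = 9)
  hi <- simulate_metaphase(60, mean_co_per_arm = 1.5, seed = 10)
  diffs <- metaphase_summary(hi, lo)
  expect_lt(diffs$p_mcn, 1e-6)
  expect_gt(diffs$groups$mean_mcn[1], diffs$groups$mean_mcn[2])

  # composition must account for every homolog pair
  bad <- data.frame(n_ring = 2L, n_rod = 1L, n_univalent_pairs = 1L)
  expect_error(metaphase_summary(bad), "expected 5")
})

test_that("cv_percent uses the sample standard deviation", {
  expect_equal(cv_percent(c(6, 8, 10)), 25)
  expect_equal(cv_percent(rep(4, 10)), 0)
  expect_error(cv_percent(c(-2, 2)), "non-positive mean")
})

test_that("detect_clusters finds planted runs and respects the threshold", {
  # 5 foci within one threshold window plus two isolated foci
  foci <- data.frame(cell_id = 1, axis_id = 1,
                     position_um = c(10, 10.3, 10.6, 10.8, 11.1, 50, 90),
                     axis_length_um = 100)
  det <- detect_clusters(foci, gap_threshold = 1/90)
  expect_identical(nrow(det$clusters), 1L)
  expect_identical(det$clusters$size, 5L)
  expect_identical(det$per_cell$max_cluster_size, 5L)

  # planted 2-focus and 3-focus groups, far-apart background
  foci2 <- data.frame(cell_id = 2, axis_id = 1,
                      position_um = c(5, 5.4, 40, 60, 60.5, 61, 95),
                      axis_length_um = 100)
  det2 <- detect_clusters(foci2, gap_threshold = 1/90)
  expect_identical(sort(det2$clusters$size), c(2L, 3L))

  # widely spaced foci: no clusters
  spread <- data.frame(cell_id = 3, axis_id = 1,
                       position_um = seq(10, 90, by = 20),
                       axis_length_um = 100)
  det3 <- detect_clusters(spread, gap_threshold = 1/90)
  expect_identical(nrow(det3$clusters), 0L)
  expect_identical(det3$per_cell$max_cluster_size, 0L)
})

test_that("cluster detection is invariant to axis rescaling", {
  foci <- simulate_foci_cells(15, clustering_mode = "clustered", seed = 20)
  scaled <- foci
  scaled$position_um <- foci$position_um * 3.5
  scaled$axis_length_um <- foci$axis_length_um * 3.5
  d1 <- detect_clusters(foci)
  d2 <- detect_clusters(scaled)
  expect_identical(d1$clusters$size, d2$clusters$size)
  expect_identical(d1$per_cell$max_cluster_size, d2$per_cell$max_cluster_size)
})

test_that("axis-fraction to DNA-distance conversion is linear and exact", {
  expect_equal(fraction_to_physical(1/400), 625)
  expect_equal(fraction_to_physical(0), 0)
  expect_equal(fraction_to_physical(1/200), 1250)
  # round trip
  kb <- fraction_to_physical(0.0137)
  expect_equal(kb / 250000, 0.0137)
  expect_equal(fraction_to_physical(c(1, 2) * 1e-3, genome_kb = 1000),
               c(1, 2))
  expect_error(fraction_to_physical(-0.1), ">= 0")
})
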