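test_that("config validation rejects impossible parameter values", {
  expect_error(sim_config(nu = 0), "nu")
  expect_error(sim_config(nu = -2), "nu")
  expect_error(sim_config(mean_co_per_bivalent = -1), "mean_co")
  expect_error(sim_config(marker_positions = c(0.3, 0.2, 0.5)), "increasing")
  expect_error(sim_config(marker_positions = c(0.3, 0.4, 1.5)), "map_length")
  expect_error(sim_config(genome_kb = 0), "genome_kb")
})

test_that("a zero-rate crossover process yields no crossovers", {
  cfg <- sim_config(mean_co_per_bivalent = 0, seed = 1)
  co <- simulate_crossover_positions(cfg, n = 50)
  expect_identical(nrow(co), 0L)
  x <- simulate_tetrad_dataset(sim_config(mean_co_per_bivalent = 0,
                                          n_tetrads = 200, seed = 1))
  expect_identical(unname(x[["a"]]), 200L) # all parental ditypes
})

test_that("crossover count dispersion is Poisson at nu = 1 and shrinks with nu", {
  n <- 100000
  disp <- vapply(c(1, 4, 10), function(nu) {
    cfg <- sim_config(nu = nu, mean_co_per_bivalent = 2, seed = 33)
    co <- simulate_crossover_positions(cfg, n = n)
    k <- tabulate(co$bivalent, nbins = n)
    stats::var(k) / mean(k)
  }, 0)
  # Poisson: variance/mean = 1 within Monte-Carlo error
  expect_lt(abs(disp[1] - 1), 0.03)
  # interference under-disperses the count, monotonically in nu
  expect_lt(disp[2], disp[1])
  expect_lt(disp[3], disp[2])
  expect_lt(disp[3], 0.7)
})

test_that("crossover draws are sorted, in range, and chromatids valid", {
  cfg <- sim_config(nu = 2, mean_co_per_bivalent = 3, seed = 9)
  co <- simulate_crossover_positions(cfg, n = 300)
  expect_true(all(co$position >= 0 & co$position < cfg$map_length))
  expect_true(all(unlist(tapply(co$position, co$bivalent,
                                function(p) !is.unsorted(p)))))
  expect_true(all(co$chromatid_a %in% 1:2))
  expect_true(all(co$chromatid_b %in% 3:4))
})

test_that("genotype_tetrad reproduces hand-traced exchange outcomes", {
  m <- c(0.1, 0.2, 0.3)
  none <- data.frame(position = numeric(0), chromatid_a = integer(0),
                     chromatid_b = integer(0))
  g0 <- genotype_tetrad(none, m)
  expect_identical(classify_tetrad(g0)$class, "a")

  # one CO between markers 1 and 2: tetratype interval 1, parental interval 2
  one <- data.frame(position = 0.15, chromatid_a = 1, chromatid_b = 3)
  g1 <- classify_tetrad(genotype_tetrad(one, m))
  expect_identical(unname(g1$status), c("T", "P"))

  # two COs in interval 1 on all four chromatids: NPD in interval 1
  four <- data.frame(position = c(0.12, 0.18),
                     chromatid_a = c(1, 2), chromatid_b = c(3, 4))
  g2 <- classify_tetrad(genotype_tetrad(four, m))
  expect_identical(g2$status[["interval1"]], "NPD")
  expect_identical(g2$status[["interval2"]], "P")

  # three-strand double across adjacent intervals is visible in both
  three <- data.frame(position = c(0.15, 0.25),
                      chromatid_a = c(1, 2), chromatid_b = c(3, 3))
  g3 <- classify_tetrad(genotype_tetrad(three, m))
  expect_identical(unname(g3$status), c("T", "T"))

  expect_error(genotype_tetrad(data.frame(position = 0.2, chromatid_a = 1,
                                          chromatid_b = 3), m), "coincides")
})

test_that("every simulated tetrad segregates 2:2 at every marker", {
  cfg <- sim_config(nu = 1, mean_co_per_bivalent = 3, seed = 21)
  co <- simulate_crossover_positions(cfg, n = 200)
  for (b in unique(co$bivalent)) {
    g <- genotype_tetrad(co[co$bivalent == b, ], cfg$marker_positions)
    expect_equal(unname(colSums(g)), c(2, 2, 2))
  }
})

test_that("tetratype frequency at nu = 1 matches the Haldane expectation", {
  cfg <- sim_config(nu = 1, mean_co_per_bivalent = 2, n_tetrads = 50000,
                    seed = 77)
  x <- simulate_tetrad_dataset(cfg)
  p1 <- interval_ptn(x, 1)
  d <- diff(cfg$marker_positions)[1] # Morgans
  t_expected <- 2 / 3 * (1 - exp(-3 * d))
  se <- sqrt(t_expected * (1 - t_expected) / p1$n_total)
  expect_lt(abs(p1$T / p1$n_total - t_expected), 3 * se)
})

test_that("fixed seeds reproduce simulations exactly", {
  cfg <- sim_config(nu = 4, n_tetrads = 500, seed = 12)
  expect_identical(simulate_tetrad_dataset(cfg), simulate_tetrad_dataset(cfg))
  f1 <- simulate_foci_cells(20, clustering_mode = "clustered", seed = 5)
  f2 <- simulate_foci_cells(20, clustering_mode = "clustered", seed = 5)
  expect_identical(f1, f2)
  expect_identical(simulate_metaphase(20, seed = 3),
                   simulate_metaphase(20, seed = 3))
})

test_that("obligate-CO resampling guarantees at least one crossover", {
  cfg <- sim_config(nu = 1, mean_co_per_bivalent = 0.5, obligate_co = TRUE,
                    seed = 6)
  co <- simulate_crossover_positions(cfg, n = 400)
  expect_identical(sort(unique(co$bivalent)), 1:400)
})

test_that("foci counts hit the requested dispersion", {
  f0 <- simulate_foci_cells(100, mean_foci = 8, dispersion = 0, seed = 1)
  expect_identical(cv_percent(as.integer(table(f0$cell_id))), 0)
  f5 <- simulate_foci_cells(400, mean_foci = 8, dispersion = 0.5, seed = 2)
  cv <- cv_percent(as.integer(table(factor(f5$cell_id, levels = 1:400))))
  expect_gt(cv, 35)
  expect_lt(cv, 65)
})

test_that("clustered foci mode plants recoverable groups", {
  f <- simulate_foci_cells(40, mean_foci = 8, clustering_mode = "clustered",
                           cluster_extent = 1/200, seed = 14)
  planted <- attr(f, "planted")
  expect_gt(nrow(planted), 10)
  det <- detect_clusters(f, gap_threshold = 1/90)
  # most planted groups are recovered as a detected cluster covering them
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    cl <- det$clusters
    any(cl$cell_id == planted$cell_id[i] &
          cl$start_um <= planted$start_um[i] + 1e-9 &
          cl$end_um >= planted$end_um[i] - 1e-9)
  }, TRUE)
  expect_gt(mean(hit), 0.8)
  expect_error(simulate_foci_cells(10, cluster_fraction = 1.2), "cluster_fraction")
})

test_that("metaphase scoring follows the ring/rod/univalent rule", {
  expect_identical(score_metaphase(cbind(rep(0, 5), rep(0, 5))),
                   data.frame(n_ring = 0L, n_rod = 0L, n_univalent_pairs = 5L))
  expect_identical(score_metaphase(cbind(rep(1, 5), rep(0, 5)))$n_rod, 5L)
  rings <- score_metaphase(cbind(c(1, 2, 1, 3, 1), c(2, 1, 1, 1, 4)))
  expect_identical(rings$n_ring, 5L)
  expect_identical(mcn(rings), 10L)
  expect_error(score_metaphase(cbind(c(-1, 0), c(0, 0))), "non-negative")
})
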