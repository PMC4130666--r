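#' Run the full synthetic-meiosis analysis pipeline
#'
#' Generates (or reads) tetrad, foci and metaphase data, runs every
#' analysis stage — Perkins distances, NPD ratios, interference ratio,
#' coefficient of coincidence, adjacent-foci cluster detection, the
#' Monte-Carlo spacing test and the metaphase summary — and writes the
#' results plus a reproducibility manifest to `out_dir`.
#'
#' @param config A named list of settings, or a path to a JSON or YAML
#'   file holding one. Recognised fields (all optional) and defaults:
#'   `seed` (1), `nu` (1), `mean_co_per_bivalent` (2), `marker_positions`
#'   (0.30, 0.39, 0.48), `map_length` (1), `n_tetrads` (10000),
#'   `n_cells` (60), `mean_foci` (8), `dispersion` (0.26),
#'   `clustering_mode` ("dispersed"), `cluster_fraction` (0.5),
#'   `cluster_extent` (1/200), `gap_threshold` (1/90), `n_sim` (10000),
#'   `n_resamples` (2000), `genome_kb` (250000), `n_pairs` (5),
#'   `mean_co_per_arm` (1), `tetrad_table`/`foci_table`/`metaphase_table`
#'   (paths; when given, that stage reads instead of simulating).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `tetrads` (counts), `interference`
#'   (NPDr per interval, IR, c.o.c.), `foci`, `clusters`, `cluster_test`,
#'   `metaphase`, `summary` and `manifest`. All seeds derive from
#'   `config$seed`, so a rerun with the same configuration is
#'   reproducible.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(list(n_tetrads = 2000, n_sim = 2000, seed = 7),
#'                     out_dir = tempfile("meiocross"))
#' out$interference$npdr_interval1$value
#' }
run_pipeline <- function(config = list(), out_dir = "meiocross-results",
                         quiet = FALSE) {
  cfg <- .pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- tetrads ---------------------------------------------------------
  counts <- stage("tetrads", {
    if (!is.null(cfg$tetrad_table)) {
      say("tetrads", "reading %s", cfg$tetrad_table)
      x <- read_tetrad_table(cfg$tetrad_table)
      if (is.list(x) && !inherits(x, "tetrad_counts")) x[[1]] else x
    } else {
      say("tetrads", "simulating %d tetrads (nu = %g)", cfg$n_tetrads, cfg$nu)
      simulate_tetrad_dataset(sim_config(
        marker_positions = cfg$marker_positions, map_length = cfg$map_length,
        nu = cfg$nu, mean_co_per_bivalent = cfg$mean_co_per_bivalent,
        n_tetrads = cfg$n_tetrads, genome_kb = cfg$genome_kb,
        seed = cfg$seed))
    }
  })
  interference <- stage("tetrad-stats", {
    ptn1 <- interval_ptn(counts, 1)
    ptn2 <- interval_ptn(counts, 2)
    list(d_interval1 = perkins_distance(ptn1),
         d_interval2 = perkins_distance(ptn2),
         npdr_interval1 = npd_ratio(ptn1, cfg$n_resamples, seed = cfg$seed + 1L),
         npdr_interval2 = npd_ratio(ptn2, cfg$n_resamples, seed = cfg$seed + 2L),
         ir = interference_ratio(counts, 1, cfg$n_resamples,
                                 seed = cfg$seed + 3L),
         coc = coefficient_of_coincidence(counts, cfg$n_resamples,
                                          seed = cfg$seed + 4L))
  })
  say("tetrad-stats", "NPDr(1) = %.3f, IR = %.3f, c.o.c. = %.3f",
      interference$npdr_interval1$value, interference$ir$value,
      interference$coc$value)

  # --- foci ------------------------------------------------------------
  foci <- stage("foci", {
    if (!is.null(cfg$foci_table)) read_foci_table(cfg$foci_table)
    else simulate_foci_cells(cfg$n_cells, cfg$mean_foci, cfg$dispersion,
                             cfg$clustering_mode, cfg$cluster_fraction,
                             cfg$cluster_extent, seed = cfg$seed + 5L)
  })
  clusters <- stage("clusters", detect_clusters(foci, cfg$gap_threshold))
  testable <- sum(clusters$clusters$size >= 3)
  ctest <- NULL
  if (testable > 0) {
    ctest <- stage("cluster-test",
                   cluster_interference_test(clusters, n_sim = cfg$n_sim,
                                             seed = cfg$seed + 6L))
    say("cluster-test", "S = %.3g over %d cluster(s), p = %.3g",
        ctest$S_total, testable, ctest$p_value)
  } else say("cluster-test", "no clusters with >= 3 foci; test skipped")

  # --- metaphase -------------------------------------------------------
  metaphase <- stage("metaphase", {
    if (!is.null(cfg$metaphase_table))
      read_metaphase_table(cfg$metaphase_table, cfg$n_pairs)
    else simulate_metaphase(cfg$n_cells, cfg$mean_co_per_arm, cfg$n_pairs,
                            seed = cfg$seed + 7L)
  })
  msum <- stage("metaphase", metaphase_summary(metaphase, n_pairs = cfg$n_pairs))

  # --- outputs ---------------------------------------------------------
  manifest <- list(package = "meiocross",
                   version = as.character(utils::packageVersion("meiocross")),
                   r_version = R.version.string,
                   seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), "seed")])
  res <- list(
    seed = cfg$seed,
    tetrads = list(counts = stats::setNames(as.integer(counts), names(counts)),
                   n_total = attr(counts, "n_total")),
    interference = list(
      d_interval1_cM = interference$d_interval1,
      d_interval2_cM = interference$d_interval2,
      npdr_interval1 = .ir_json(interference$npdr_interval1),
      npdr_interval2 = .ir_json(interference$npdr_interval2),
      interference_ratio = .ir_json(interference$ir),
      coefficient_of_coincidence = .ir_json(interference$coc)),
    foci = list(n_cells = length(unique(foci$cell_id)),
                cv_percent = if (length(unique(foci$cell_id)) >= 2)
                  cv_percent(as.integer(table(foci$cell_id))) else NA,
                n_clusters = nrow(clusters$clusters),
                cluster_test = if (!is.null(ctest))
                  list(S_total = ctest$S_total, p_value = ctest$p_value,
                       n_sim = ctest$n_sim, n_clusters = nrow(ctest$per_cluster))
                else NULL),
    metaphase = list(mean_mcn = msum$groups$mean_mcn[1],
                     sd_mcn = msum$groups$sd_mcn[1],
                     mean_bivalents = msum$groups$mean_bivalents[1]))
  write_tetrad_table(counts, file.path(out_dir, "tetrads.tsv"))
  write_foci_table(foci, file.path(out_dir, "foci.tsv"))
  utils::write.table(metaphase, file.path(out_dir, "metaphase.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", "results written to %s", out_dir)
  invisible(list(tetrads = counts, interference = interference, foci = foci,
                 clusters = clusters, cluster_test = ctest,
                 metaphase = metaphase, summary = res, manifest = manifest))
}

.ir_json <- function(x) {
  list(value = x$value, se = x$se, ci95 = x$ci, p_vs_1 = x$p_vs_1,
       components = x$components, n_resamples = x$n_resamples)
}

.pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stopf("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stopf("'config' must be a list or a file path")
  defaults <- list(seed = 1L, nu = 1, mean_co_per_bivalent = 2,
                   marker_positions = c(0.30, 0.39, 0.48), map_length = 1,
                   n_tetrads = 10000L, n_cells = 60L, mean_foci = 8,
                   dispersion = 0.26, clustering_mode = "dispersed",
                   cluster_fraction = 0.5, cluster_extent = 1/200,
                   gap_threshold = 1/90, n_sim = 10000L, n_resamples = 2000L,
                   genome_kb = 250000, n_pairs = 5L, mean_co_per_arm = 1,
                   tetrad_table = NULL, foci_table = NULL,
                   metaphase_table = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(check_scalar(cfg$seed, "seed", integer = TRUE))
  for (f in c("gap_threshold", "cluster_extent"))
    check_scalar(cfg[[f]], f, 0, strict = TRUE)
  cfg
}
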