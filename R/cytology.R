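#' Minimum chiasma number of a metaphase I cell
#'
#' Scores a rod bivalent (chiasmata on one chromosome arm) as one chiasma
#' and a ring bivalent (chiasmata on both arms) as two; univalent pairs
#' contribute none. The result is the minimum number of chiasmata
#' compatible with the observed configuration.
#'
#' @param n_ring Ring-bivalent counts, or a data frame with columns
#'   `n_ring` and `n_rod` (e.g. from [simulate_metaphase()] or
#'   [read_metaphase_table()]).
#' @param n_rod Rod-bivalent counts (ignored when `n_ring` is a data
#'   frame).
#' @return Integer vector of per-cell minimum chiasma numbers.
#' @export
#' @examples
#' mcn(n_ring = 3, n_rod = 2) # 8
mcn <- function(n_ring, n_rod = NULL) {
  if (is.data.frame(n_ring)) {
    if (!all(c("n_ring", "n_rod") %in% names(n_ring)))
      stopf("data frame must have columns n_ring and n_rod")
    n_rod <- n_ring$n_rod
    n_ring <- n_ring$n_ring
  }
  if (is.null(n_rod)) stopf("'n_rod' is missing")
  if (any(n_ring < 0) || any(n_rod < 0)) stopf("bivalent counts must be >= 0")
  as.integer(n_rod + 2L * n_ring)
}

#' Summarise metaphase I configurations, optionally comparing two groups
#'
#' Computes per-group means and standard deviations of the bivalent count
#' and the minimum chiasma number ([mcn()]), and, when two groups are
#' supplied, Welch two-sample comparisons of both quantities.
#'
#' @param x A data frame of per-cell counts with columns `n_ring`,
#'   `n_rod`, `n_univalent_pairs`.
#' @param y Optional second data frame (same columns) to compare against.
#' @param n_pairs Chromosome (homolog pair) number; every cell's
#'   composition must sum to it (5 for *A. thaliana*).
#' @return An object of class `"metaphase_summary"`: a list with a
#'   `groups` data frame (n, mean/sd of MCN and bivalents) and, for two
#'   groups, `p_mcn` and `p_bivalents` from Welch t-tests.
#' @export
#' @examples
#' wt <- simulate_metaphase(40, mean_co_per_arm = 1.2, seed = 1)
#' mut <- simulate_metaphase(40, mean_co_per_arm = 0.4, seed = 2)
#' metaphase_summary(wt, mut)
metaphase_summary <- function(x, y = NULL, n_pairs = 5) {
  groups <- list(group1 = x)
  if (!is.null(y)) groups$group2 <- y
  per <- lapply(groups, function(g) {
    .check_metaphase(g, n_pairs)
    data.frame(n = nrow(g),
               mean_mcn = mean(mcn(g)), sd_mcn = stats::sd(mcn(g)),
               mean_bivalents = mean(g$n_ring + g$n_rod),
               sd_bivalents = stats::sd(g$n_ring + g$n_rod))
  })
  out <- list(groups = cbind(group = names(per), do.call(rbind, per)),
              p_mcn = NA_real_, p_bivalents = NA_real_)
  rownames(out$groups) <- NULL
  if (!is.null(y)) {
    if (nrow(x) < 2 || nrow(y) < 2)
      stopf("two-group comparison needs at least 2 cells per group")
    out$p_mcn <- stats::t.test(mcn(x), mcn(y))$p.value
    out$p_bivalents <- stats::t.test(x$n_ring + x$n_rod,
                                     y$n_ring + y$n_rod)$p.value
  }
  structure(out, class = "metaphase_summary")
}

.check_metaphase <- function(g, n_pairs) {
  need <- c("n_ring", "n_rod", "n_univalent_pairs")
  if (!is.data.frame(g) || !all(need %in% names(g)))
    stopf("metaphase data must have columns %s", paste(need, collapse = ", "))
  if (nrow(g) == 0) stopf("empty metaphase group")
  if (any(g[need] < 0)) stopf("metaphase counts must be >= 0")
  tot <- g$n_ring + g$n_rod + g$n_univalent_pairs
  bad <- which(tot != n_pairs)
  if (length(bad))
    stopf("cell %d: composition sums to %d, expected %d homolog pairs",
          bad[1], tot[bad[1]], n_pairs)
  invisible(g)
}

#' @export
print.metaphase_summary <- function(x, digits = 3, ...) {
  cat("Metaphase I summary (MCN: rod = 1 chiasma, ring = 2)\n")
  print(x$groups, digits = digits, row.names = FALSE)
  if (!is.na(x$p_mcn))
    cat(sprintf("  Welch t: MCN p = %.3g, bivalents p = %.3g\n",
                x$p_mcn, x$p_bivalents))
  invisible(x)
}

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation; used
#' to quantify cell-to-cell variability of focus counts.
#'
#' @param x Numeric vector with positive mean.
#' @return The CV as a percentage.
#' @export
#' @examples
#' cv_percent(c(6, 8, 10)) # 25
cv_percent <- function(x) {
  if (length(x) < 2) stopf("need at least 2 observations")
  m <- mean(x)
  if (m <= 0) stopf("CV is undefined for non-positive mean")
  100 * stats::sd(x) / m
}

#' Detect clusters of adjacent foci along chromosome axes
#'
#' Finds maximal runs of two or more consecutive foci on the same axis
#' whose successive gaps are each smaller than a threshold fraction of
#' the total axis length. The default threshold, 1/90 of the axis,
#' corresponds to the largest intra-cluster gap observed cytologically;
#' because it is a fraction, detection is invariant to rescaling of the
#' axis.
#'
#' @param foci A data frame with columns `cell_id`, `axis_id`,
#'   `position_um`, `axis_length_um` (e.g. from [simulate_foci_cells()]
#'   or [read_foci_table()]).
#' @param gap_threshold Maximal intra-cluster gap, as a fraction of the
#'   axis length (> 0).
#' @return An object of class `"foci_clusters"`: a list with
#'   * `clusters`: one row per cluster (`cell_id`, `axis_id`, `size`,
#'     `start_um`, `end_um`, `span_um`, `span_fraction`) plus a
#'     `positions` list column with the member foci;
#'   * `per_cell`: one row per cell (`cell_id`, `n_foci`, `n_clusters`,
#'     `max_cluster_size`, 0 when no cluster);
#'   * `gap_threshold`.
#'   The `per_cell$max_cluster_size` column tabulates into the
#'   cells-with-0/2/3/... adjacent-foci histogram used to describe
#'   clustering phenotypes.
#' @export
#' @examples
#' foci <- simulate_foci_cells(10, clustering_mode = "clustered", seed = 9)
#' detect_clusters(foci)$per_cell
detect_clusters <- function(foci, gap_threshold = 1/90) {
  need <- c("cell_id", "axis_id", "position_um", "axis_length_um")
  if (!is.data.frame(foci) || !all(need %in% names(foci)))
    stopf("'foci' must have columns %s", paste(need, collapse = ", "))
  check_scalar(gap_threshold, "gap_threshold", 0, strict = TRUE)
  cl_rows <- list()
  cells <- unique(foci$cell_id)
  per_cell <- data.frame(cell_id = cells, n_foci = 0L, n_clusters = 0L,
                         max_cluster_size = 0L)
  for (ci in seq_along(cells)) {
    fc <- foci[foci$cell_id == cells[ci], ]
    per_cell$n_foci[ci] <- nrow(fc)
    for (ax in unique(fc$axis_id)) {
      fa <- fc[fc$axis_id == ax, ]
      p <- sort(fa$position_um)
      L <- fa$axis_length_um[1]
      if (length(p) < 2) next
      close_gap <- diff(p) < gap_threshold * L
      runs <- rle(close_gap)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        i0 <- starts[r]; i1 <- ends[r] + 1L
        member <- p[i0:i1]
        cl_rows[[length(cl_rows) + 1]] <- list(
          cell_id = cells[ci], axis_id = ax, size = length(member),
          start_um = member[1], end_um = member[length(member)],
          span_um = member[length(member)] - member[1],
          span_fraction = (member[length(member)] - member[1]) / L,
          positions = member)
      }
    }
  }
  if (length(cl_rows)) {
    grab <- function(f) sapply(cl_rows, `[[`, f)
    clusters <- data.frame(
      cell_id = grab("cell_id"), axis_id = grab("axis_id"),
      size = as.integer(grab("size")), start_um = grab("start_um"),
      end_um = grab("end_um"), span_um = grab("span_um"),
      span_fraction = grab("span_fraction"))
    clusters$positions <- lapply(cl_rows, `[[`, "positions")
    lev <- factor(clusters$cell_id, levels = cells)
    per_cell$n_clusters <- as.integer(table(lev))
    mx <- tapply(clusters$size, lev, max)
    per_cell$max_cluster_size <- as.integer(ifelse(is.na(mx), 0L, mx))
  } else {
    clusters <- data.frame(cell_id = numeric(0), axis_id = integer(0),
                           size = integer(0), start_um = numeric(0),
                           end_um = numeric(0), span_um = numeric(0),
                           span_fraction = numeric(0))
    clusters$positions <- list()
  }
  structure(list(clusters = clusters, per_cell = per_cell,
                 gap_threshold = gap_threshold),
            class = "foci_clusters")
}

#' @export
print.foci_clusters <- function(x, ...) {
  cat(sprintf("Adjacent-foci clusters (gap threshold %.4g of axis length)\n",
              x$gap_threshold))
  cat(sprintf("  %d cluster(s) in %d of %d cell(s)\n",
              nrow(x$clusters), sum(x$per_cell$n_clusters > 0),
              nrow(x$per_cell)))
  if (nrow(x$clusters)) {
    cat("  cells by largest adjacent-foci run (0 = none):\n")
    print(table(x$per_cell$max_cluster_size))
  }
  invisible(x)
}

#' Convert an axis/genome fraction to physical DNA distance
#'
#' Under the assumption that chromatin condensation is homogeneous along
#' the axis, a fraction of the total axis corresponds to the same
#' fraction of the genome. The default genome length of 250,000 kb
#' (250 Mb) is the constant consistent with converting a mean adjacent-
#' focus spacing of 1/400 of the axis into 625 kb.
#'
#' @param fraction Non-negative fraction(s) of the genome/axis.
#' @param genome_kb Physical genome length in kb.
#' @return Physical distance(s) in kb.
#' @export
#' @examples
#' fraction_to_physical(1/400) # 625 kb
fraction_to_physical <- function(fraction, genome_kb = 250000) {
  if (any(fraction < 0)) stopf("'fraction' must be >= 0")
  check_scalar(genome_kb, "genome_kb", 0, strict = TRUE)
  fraction * genome_kb
}
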