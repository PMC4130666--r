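#' Configuration for the synthetic meiosis simulator
#'
#' Bundles and validates the parameters of the gamma-renewal crossover
#' process and the tetrad/foci/metaphase generators built on top of it.
#'
#' @param marker_positions Genetic positions (Morgans from the chromosome
#'   start) of the three ordered fluorescent markers; strictly increasing,
#'   within `[0, map_length]`. The defaults place two ~9 cM intervals in
#'   the middle of the bivalent.
#' @param map_length Total genetic length of the bivalent, in Morgans.
#' @param nu Shape of the gamma-renewal inter-crossover distribution.
#'   `nu = 1` gives a homogeneous Poisson process (no interference);
#'   `nu > 1` makes crossovers more evenly spaced (interference);
#'   `0 < nu < 1` clusters them (negative interference).
#' @param mean_co_per_bivalent Expected number of crossovers per bivalent.
#'   With `mean_co_per_bivalent = 2 * map_length` the genetic coordinates
#'   are true Morgans (one CO per bivalent contributes 50 cM).
#' @param n_tetrads,n_cells Sample sizes for the tetrad and cytology
#'   generators.
#' @param genome_kb Physical genome length constant (kb) used when
#'   converting axis fractions to DNA distances; see
#'   [fraction_to_physical()].
#' @param obligate_co If `TRUE`, bivalents are resampled until they carry
#'   at least one crossover (the "obligatory CO"). Off by default because
#'   mutants that lose the obligatory CO are a use case of interest.
#' @param seed Optional RNG seed recorded with the configuration and used
#'   by the generators.
#' @return An object of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(nu = 1, n_tetrads = 500, seed = 1)
sim_config <- function(marker_positions = c(0.30, 0.39, 0.48),
                       map_length = 1,
                       nu = 1,
                       mean_co_per_bivalent = 2,
                       n_tetrads = 1000,
                       n_cells = 100,
                       genome_kb = 250000,
                       obligate_co = FALSE,
                       seed = NULL) {
  check_scalar(map_length, "map_length", 0, strict = TRUE)
  check_scalar(nu, "nu", 0, strict = TRUE)
  check_scalar(mean_co_per_bivalent, "mean_co_per_bivalent", 0)
  check_scalar(n_tetrads, "n_tetrads", 0, integer = TRUE)
  check_scalar(n_cells, "n_cells", 0, integer = TRUE)
  check_scalar(genome_kb, "genome_kb", 0, strict = TRUE)
  if (!is.numeric(marker_positions) || length(marker_positions) != 3L)
    stopf("'marker_positions' must give 3 genetic positions")
  if (any(diff(marker_positions) <= 0))
    stopf("'marker_positions' must be strictly increasing")
  if (marker_positions[1] < 0 || marker_positions[3] > map_length)
    stopf("'marker_positions' must lie within [0, map_length]")
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)
  structure(list(marker_positions = as.numeric(marker_positions),
                 map_length = map_length, nu = nu,
                 mean_co_per_bivalent = mean_co_per_bivalent,
                 n_tetrads = as.integer(n_tetrads),
                 n_cells = as.integer(n_cells),
                 genome_kb = genome_kb,
                 obligate_co = isTRUE(obligate_co),
                 seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic meiosis configuration\n")
  cat(sprintf("  markers (M): %s  map length: %g M\n",
              paste(format(x$marker_positions), collapse = ", "),
              x$map_length))
  cat(sprintf("  nu = %g, mean COs/bivalent = %g%s\n", x$nu,
              x$mean_co_per_bivalent,
              if (x$obligate_co) " (obligate CO)" else ""))
  cat(sprintf("  n_tetrads = %d, n_cells = %d, genome = %g kb, seed = %s\n",
              x$n_tetrads, x$n_cells, x$genome_kb,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

# Event positions of a stationary gamma-renewal process, one row per draw.
# Stationarity is obtained by starting the renewal sequence `burnin` mean
# spacings before the window of interest and discarding the run-in.
# Returns an n x k matrix of positions in [0, len), padded with NA.
.renewal_events <- function(n, nu, rate, len) {
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  if (rate <= 0 || len <= 0) return(matrix(NA_real_, n, 0))
  burn <- 10 / rate
  win <- burn + len
  m <- win * rate
  nc <- ceiling(m + 10 * sqrt(m / min(nu, 1)) + 10)
  cum <- .renewal_cumsums(n, nu, rate, win, nc)
  cum <- cum - burn
  cum[!is.na(cum) & (cum < 0 | cum >= len)] <- NA_real_
  # left-align the surviving events per row
  k <- rowSums(!is.na(cum))
  kmax <- max(k, 0L)
  out <- matrix(NA_real_, n, kmax)
  if (kmax > 0) {
    idx <- which(!is.na(cum), arr.ind = TRUE)
    ord <- order(idx[, 1], cum[idx])
    idx <- idx[ord, , drop = FALSE]
    col <- sequence(k[k > 0])
    out[cbind(idx[, 1], col)] <- cum[idx]
  }
  out
}

# cumulative gamma inter-arrival sums guaranteed to cover [0, win]
.renewal_cumsums <- function(n, nu, rate, win, nc) {
  x <- matrix(stats::rgamma(n * nc, shape = nu, rate = nu * rate), n, nc)
  if (nc > 1) for (j in 2:nc) x[, j] <- x[, j - 1] + x[, j]
  short <- which(x[, nc] < win)
  while (length(short)) {
    add <- matrix(stats::rgamma(length(short) * nc, shape = nu, rate = nu * rate),
                  length(short), nc)
    add[, 1] <- add[, 1] + x[short, ncol(x)]
    if (nc > 1) for (j in 2:nc) add[, j] <- add[, j - 1] + add[, j]
    pad <- matrix(NA_real_, n, nc)
    pad[short, ] <- add
    # events beyond win are never used, so NA padding elsewhere is safe
    x <- cbind(x, pad)
    short <- short[add[, nc] < win]
    nc2 <- ncol(x)
    if (nc2 > 10000) stopf("renewal simulation failed to cover the window")
  }
  x
}

#' Simulate crossover positions on bivalents
#'
#' Draws crossover (CO) positions from a stationary gamma-renewal process
#' along the genetic map, together with the pair of non-sister chromatids
#' engaged by each CO. The renewal shape `nu` controls interference:
#' `nu = 1` reduces to a homogeneous Poisson process, larger `nu` gives
#' increasingly even spacing (and an under-dispersed CO count per
#' bivalent). Chromatids are drawn uniformly and independently per CO
#' (no chromatid interference): one of the two chromatids of each homolog
#' (1/2 for the marked homolog, 3/4 for the unmarked one).
#'
#' @param config A [sim_config()].
#' @param n Number of bivalents to draw.
#' @return A data frame with one row per crossover: `bivalent` (draw
#'   index, 1..n; bivalents without COs contribute no rows), `position`
#'   (Morgans, sorted within bivalent), `chromatid_a` (1 or 2) and
#'   `chromatid_b` (3 or 4).
#' @export
#' @examples
#' cfg <- sim_config(nu = 10, n_tetrads = 10, seed = 7)
#' simulate_crossover_positions(cfg, n = 3)
simulate_crossover_positions <- function(config, n = 1) {
  stopifnot(inherits(config, "sim_config"))
  check_scalar(n, "n", 0, integer = TRUE)
  with_seed_or_not(config$seed, .sim_co(config, n, lo = 0, hi = config$map_length))
}

# internal: CO draws restricted to [lo, hi); obligate-CO resampling judges
# presence on the full bivalent [0, map_length)
.sim_co <- function(config, n, lo = 0, hi = config$map_length) {
  rate <- config$mean_co_per_bivalent / config$map_length
  pos <- .renewal_events(n, config$nu, rate, config$map_length)
  if (config$obligate_co && rate > 0) {
    empty <- which(rowSums(!is.na(pos)) == 0)
    while (length(empty)) {
      res <- .renewal_events(length(empty), config$nu, rate, config$map_length)
      if (ncol(res) > ncol(pos))
        pos <- cbind(pos, matrix(NA_real_, nrow(pos), ncol(res) - ncol(pos)))
      pos[empty, seq_len(ncol(res))] <- res
      empty <- empty[rowSums(!is.na(res)) == 0]
    }
  }
  keep <- !is.na(pos) & pos >= lo & pos < hi
  k <- rowSums(keep)
  biv <- rep(seq_len(n), times = k)
  position <- t(pos)[t(keep)]
  data.frame(bivalent = biv,
             position = position,
             chromatid_a = sample(1:2, length(biv), replace = TRUE),
             chromatid_b = sample(3:4, length(biv), replace = TRUE))
}

#' Derive the four spore genotypes of a tetrad from its crossovers
#'
#' Propagates marker alleles through a set of crossovers on one bivalent.
#' The four chromatids start as two carrying all three markers (chromatids
#' 1, 2; the marked homolog) and two carrying none (3, 4). Each crossover
#' exchanges the chromosome segments distal to its position between the
#' two chromatids it engages, so a marker is inherited from whichever
#' homolog the chromatid tracks at the marker's position.
#'
#' @param crossovers A data frame with columns `position`, `chromatid_a`
#'   (1 or 2) and `chromatid_b` (3 or 4), e.g. one bivalent's rows from
#'   [simulate_crossover_positions()]. Zero rows give a parental ditype.
#' @param marker_positions The three marker positions (Morgans).
#' @return A 4 x 3 integer matrix of marker presences (rows = spores in
#'   chromatid order, columns = markers); every column sums to 2.
#' @details A crossover exactly coincident with a marker position has no
#'   defined side; such configurations are rejected with an error (they
#'   occur with probability zero in the continuous model and are
#'   resampled internally by [simulate_tetrad_dataset()]).
#' @export
#' @examples
#' co <- data.frame(position = 0.35, chromatid_a = 1, chromatid_b = 3)
#' genotype_tetrad(co, marker_positions = c(0.30, 0.39, 0.48))
genotype_tetrad <- function(crossovers, marker_positions) {
  if (!is.data.frame(crossovers) ||
      !all(c("position", "chromatid_a", "chromatid_b") %in% names(crossovers)))
    stopf("'crossovers' must have columns position, chromatid_a, chromatid_b")
  if (length(marker_positions) != 3L || any(diff(marker_positions) <= 0))
    stopf("'marker_positions' must be 3 strictly increasing positions")
  if (any(crossovers$position %in% marker_positions))
    stopf("crossover position coincides with a marker position")
  if (!all(crossovers$chromatid_a %in% 1:2) ||
      !all(crossovers$chromatid_b %in% 3:4))
    stopf("chromatid_a must be 1/2 and chromatid_b must be 3/4")
  # src[l, m]: TRUE if the molecule anchored at centromere l lies on a
  # chromatid of the marked homolog at marker m. A crossover joins one
  # structural chromatid of each homolog (slots 1/2 and 3/4); the two
  # molecules currently travelling on those slots exchange paths distal
  # to the exchange point, so occupancy must be tracked through
  # successive crossovers.
  src <- matrix(rep(c(TRUE, TRUE, FALSE, FALSE), 3), 4, 3)
  occ <- 1:4 # occ[slot]: molecule currently on that slot
  ord <- order(crossovers$position)
  for (r in ord) {
    sa <- crossovers$chromatid_a[r]; sb <- crossovers$chromatid_b[r]
    la <- occ[sa]; lb <- occ[sb]
    distal <- marker_positions > crossovers$position[r]
    if (any(distal)) {
      tmp <- src[la, distal]
      src[la, distal] <- src[lb, distal]
      src[lb, distal] <- tmp
    }
    occ[sa] <- lb; occ[sb] <- la
  }
  out <- src * 1L
  dimnames(out) <- list(paste0("spore", 1:4), paste0("marker", 1:3))
  out
}

#' Simulate and classify a tetrad dataset
#'
#' Draws `config$n_tetrads` meioses from the crossover process, genotypes
#' the resulting tetrads at the three markers, classifies each into the
#' twelve phenotype classes and tallies the counts.
#'
#' @param config A [sim_config()].
#' @return A [tetrad_counts] object (named integer vector of class counts
#'   `a`-`l`) with the configuration stored in `attr(, "config")`.
#' @export
#' @examples
#' cfg <- sim_config(nu = 1, n_tetrads = 2000, seed = 11)
#' x <- simulate_tetrad_dataset(cfg)
#' interval_ptn(x, 1)
simulate_tetrad_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_tetrads
  cls <- with_seed_or_not(config$seed, .sim_tetrad_classes(config, n))
  counts <- table(cls)
  out <- tetrad_counts(as.integer(counts))
  attr(out, "config") <- config
  out
}

# classify n simulated tetrads; only crossovers strictly between the first
# and last marker can alter the spore phenotype multiset (a CO proximal to
# all markers swaps two whole marker haplotypes, a permutation of spores),
# so the simulation window is restricted to (m1, m3) for speed.
.sim_tetrad_classes <- function(config, n) {
  m <- config$marker_positions
  if (n == 0L) return(factor(character(0), levels = .tc$class))
  repeat {
    co <- .sim_co(config, n, lo = m[1], hi = m[3])
    if (!any(co$position %in% m)) break # measure-zero: resample whole draw
  }
  # src[t, (molecule-1)*3 + marker]: TRUE if molecule tracks the marked
  # homolog at that marker; occ[t, slot]: molecule currently travelling
  # on that structural chromatid (each crossover swaps the two molecules
  # on the slots it joins, distal to its position)
  src <- matrix(rep(c(TRUE, TRUE, FALSE, FALSE), each = 3 * n), n, 12)
  occ <- matrix(rep(1:4, each = n), n, 4)
  if (nrow(co)) {
    ord <- order(co$bivalent, co$position)
    co <- co[ord, , drop = FALSE]
    rank_in_biv <- sequence(rle(co$bivalent)$lengths)
    for (j in seq_len(max(rank_in_biv))) {
      rows <- which(rank_in_biv == j)
      biv <- co$bivalent[rows]
      ia <- cbind(biv, co$chromatid_a[rows])
      ib <- cbind(biv, co$chromatid_b[rows])
      la <- occ[ia]; lb <- occ[ib]
      for (mk in 2:3) { # marker 1 is never distal to a CO in (m1, m3)
        distal <- m[mk] > co$position[rows]
        if (!any(distal)) next
        sa <- cbind(biv[distal], (la[distal] - 1L) * 3L + mk)
        sb <- cbind(biv[distal], (lb[distal] - 1L) * 3L + mk)
        tmp <- src[sa]
        src[sa] <- src[sb]
        src[sb] <- tmp
      }
      occ[ia] <- lb; occ[ib] <- la
    }
  }
  # spore phenotype codes and row-sorted keys
  code <- matrix(0L, n, 4)
  for (ch in 1:4)
    code[, ch] <- src[, (ch - 1L) * 3L + 1L] * 4L +
      src[, (ch - 1L) * 3L + 2L] * 2L + src[, (ch - 1L) * 3L + 3L]
  lo1 <- pmin(code[, 1], code[, 2]); hi1 <- pmax(code[, 1], code[, 2])
  lo2 <- pmin(code[, 3], code[, 4]); hi2 <- pmax(code[, 3], code[, 4])
  s1 <- pmin(lo1, lo2); t4 <- pmax(hi1, hi2)
  mid1 <- pmax(lo1, lo2); mid2 <- pmin(hi1, hi2)
  s2 <- pmin(mid1, mid2); s3 <- pmax(mid1, mid2)
  .classify_keys(cbind(s1, s2, s3, t4))
}

#' Simulate per-cell recombination focus positions along chromosome axes
#'
#' Generates synthetic immunostained-focus data emulating either a
#' wild-type-like pattern (foci spread out along the axis) or a
#' mutant-like pattern in which a fraction of foci fall into tight
#' clusters. Per-cell focus counts are drawn with a tunable coefficient
#' of variation.
#'
#' @param n_cells Number of cells.
#' @param mean_foci Mean focus count per cell (default 8, a typical class
#'   I CO count per *Arabidopsis* meiocyte).
#' @param dispersion Target coefficient of variation of the focus counts
#'   (SD/mean); counts are a rounded normal clamped at 0. Default 0.26,
#'   a wild-type-like value; mutant-like data are around 0.5.
#' @param clustering_mode `"dispersed"` (evenly spaced with jitter) or
#'   `"clustered"` (a fraction of foci placed in tight groups).
#' @param cluster_fraction Fraction of foci assigned to clusters in
#'   `"clustered"` mode (in `[0, 1]`).
#' @param cluster_extent Maximal span of a cluster as a fraction of the
#'   axis length (default 1/200).
#' @param axis_length_um Total axis length per cell (micrometres).
#' @param jitter Positional jitter of dispersed foci, as a fraction of the
#'   mean inter-focus spacing.
#' @param seed Optional RNG seed.
#' @return A data frame (`cell_id`, `axis_id`, `position_um`,
#'   `axis_length_um`), positions sorted within cell. In clustered mode
#'   the planted groups are recorded in `attr(, "planted")` (cell, group
#'   size, window start/end) for validation studies.
#' @export
#' @examples
#' foci <- simulate_foci_cells(5, clustering_mode = "clustered", seed = 3)
#' head(foci)
simulate_foci_cells <- function(n_cells,
                                mean_foci = 8,
                                dispersion = 0.26,
                                clustering_mode = c("dispersed", "clustered"),
                                cluster_fraction = 0.5,
                                cluster_extent = 1/200,
                                axis_length_um = 150,
                                jitter = 0.25,
                                seed = NULL) {
  check_scalar(n_cells, "n_cells", 0, integer = TRUE)
  check_scalar(mean_foci, "mean_foci", 0, strict = TRUE)
  check_scalar(dispersion, "dispersion", 0)
  check_scalar(axis_length_um, "axis_length_um", 0, strict = TRUE)
  clustering_mode <- match.arg(clustering_mode)
  if (cluster_fraction < 0 || cluster_fraction > 1)
    stopf("'cluster_fraction' must be in [0, 1]")
  check_scalar(cluster_extent, "cluster_extent", 0, strict = TRUE)
  with_seed_or_not(seed, {
    counts <- pmax(0L, as.integer(round(stats::rnorm(n_cells, mean_foci,
                                                     dispersion * mean_foci))))
    L <- axis_length_um
    planted <- list()
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      nf <- counts[i]
      if (nf == 0L) next
      if (clustering_mode == "dispersed") {
        pos <- .dispersed_positions(nf, L, jitter)
      } else {
        n_clustered <- round(cluster_fraction * nf)
        sizes <- integer(0)
        while (sum(sizes) < n_clustered - 1) {
          s <- sample(2:5, 1, prob = c(0.55, 0.25, 0.13, 0.07))
          sizes <- c(sizes, min(s, max(2, n_clustered - sum(sizes))))
        }
        sizes <- sizes[sizes >= 2]
        n_free <- nf - sum(sizes)
        if (n_free < 0) { sizes <- sizes[-length(sizes)]; n_free <- nf - sum(sizes) }
        pos <- if (n_free > 0) .dispersed_positions(n_free, L, jitter) else numeric(0)
        w <- cluster_extent * L
        for (s in sizes) {
          centre <- stats::runif(1, w / 2, L - w / 2)
          member <- sort(stats::runif(s, centre - w / 2, centre + w / 2))
          pos <- c(pos, member)
          planted[[length(planted) + 1]] <-
            data.frame(cell_id = i, size = s,
                       start_um = member[1], end_um = member[s])
        }
      }
      rows[[i]] <- data.frame(cell_id = i, axis_id = 1L,
                              position_um = sort(pos),
                              axis_length_um = L)
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(cell_id = integer(0), axis_id = integer(0),
                 position_um = numeric(0), axis_length_um = numeric(0))
    rownames(out) <- NULL
    if (clustering_mode == "clustered")
      attr(out, "planted") <- if (length(planted)) do.call(rbind, planted) else
        data.frame(cell_id = integer(0), size = integer(0),
                   start_um = numeric(0), end_um = numeric(0))
    out
  })
}

.dispersed_positions <- function(nf, L, jitter) {
  base <- (seq_len(nf) - 0.5) / nf * L
  p <- base + stats::rnorm(nf, 0, jitter * L / max(nf, 1))
  pmin(pmax(p, 0), L)
}

#' Score a metaphase I cell from per-arm crossover counts
#'
#' Applies the cytological scoring rule: a homolog pair with no crossover
#' appears as a univalent pair, crossovers on exactly one chromosome arm
#' give a rod bivalent, and crossovers on both arms give a ring bivalent.
#'
#' @param arm_co A matrix with one row per homolog pair and two columns of
#'   non-negative per-arm crossover counts.
#' @return A one-row data frame: `n_ring`, `n_rod`, `n_univalent_pairs`.
#' @export
#' @examples
#' score_metaphase(cbind(c(1, 1, 0, 2, 0), c(1, 0, 0, 1, 0)))
score_metaphase <- function(arm_co) {
  arm_co <- as.matrix(arm_co)
  if (ncol(arm_co) != 2L) stopf("'arm_co' must have two columns (one per arm)")
  if (any(arm_co < 0) || any(arm_co != round(arm_co)))
    stopf("per-arm crossover counts must be non-negative integers")
  both <- rowSums(arm_co > 0)
  data.frame(n_ring = sum(both == 2L),
             n_rod = sum(both == 1L),
             n_univalent_pairs = sum(both == 0L))
}

#' Simulate metaphase I bivalent configurations
#'
#' Draws per-arm crossover counts (Poisson) for each homolog pair of each
#' cell and scores ring/rod/univalent configurations with
#' [score_metaphase()].
#'
#' @param n_cells Number of cells.
#' @param mean_co_per_arm Mean crossover count per chromosome arm.
#' @param n_pairs Number of homolog pairs per cell (5 for *A. thaliana*).
#' @param seed Optional RNG seed.
#' @return A data frame with columns `cell_id`, `n_ring`, `n_rod`,
#'   `n_univalent_pairs`.
#' @export
#' @examples
#' simulate_metaphase(4, mean_co_per_arm = 1, seed = 5)
simulate_metaphase <- function(n_cells, mean_co_per_arm = 1, n_pairs = 5,
                               seed = NULL) {
  check_scalar(n_cells, "n_cells", 0, integer = TRUE)
  check_scalar(mean_co_per_arm, "mean_co_per_arm", 0)
  check_scalar(n_pairs, "n_pairs", 1, integer = TRUE)
  with_seed_or_not(seed, {
    arm <- matrix(stats::rpois(n_cells * n_pairs * 2, mean_co_per_arm),
                  ncol = 2)
    cell <- rep(seq_len(n_cells), each = n_pairs)
    both <- rowSums(arm > 0)
    data.frame(cell_id = seq_len(n_cells),
               n_ring = as.integer(tapply(both == 2, cell, sum)),
               n_rod = as.integer(tapply(both == 1, cell, sum)),
               n_univalent_pairs = as.integer(tapply(both == 0, cell, sum)),
               row.names = NULL)
  })
}
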