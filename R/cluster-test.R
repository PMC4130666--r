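#' Normalised gaps between ordered foci
#'
#' Converts the positions of the foci in one cluster into the vector of
#' adjacent distances, normalised by the span between the outermost two
#' foci so that the gaps sum to 1. A cluster with `k + 2` foci yields
#' `k + 1` gaps; only the `k` internal foci are informative about spacing
#' regularity.
#'
#' @param positions Numeric vector of at least 3 focus positions (any
#'   units; the statistic is invariant to affine rescaling).
#' @return Numeric vector of `length(positions) - 1` gaps summing to 1.
#'   Duplicate positions give zero gaps, which are allowed but flagged
#'   with a warning.
#' @export
#' @examples
#' normalize_gaps(c(0, 2, 10)) # 0.2 0.8
normalize_gaps <- function(positions) {
  if (!is.numeric(positions) || length(positions) < 3)
    stopf("a testable cluster needs at least 3 foci, got %d", length(positions))
  p <- sort(positions)
  span <- p[length(p)] - p[1]
  if (span == 0) stopf("degenerate cluster: all foci at the same position")
  gaps <- diff(p) / span
  if (any(gaps == 0)) warnf("duplicate focus positions give zero-width gaps")
  gaps
}

#' Spacing-regularity statistic for one cluster
#'
#' The sum of squared deviations of the normalised gaps from equal
#' spacing, scaled by the variance of a gap under the null hypothesis
#' that the internal foci are uniformly distributed:
#' `S = sum((d_i - 1/(k+1))^2) * (k+1)^2 * (k+2) / k` for `k + 1` gaps.
#' Under uniformity each gap contributes 1 on average, so `E[S] = k + 1`
#' regardless of cluster size; `S = 0` means perfectly even spacing.
#'
#' @param gaps Normalised gap vector from [normalize_gaps()] (at least 2
#'   gaps, i.e. `k >= 1` internal foci).
#' @return The statistic S (non-negative scalar).
#' @export
#' @examples
#' cluster_statistic(c(0.2, 0.8)) # 12 * (0.09 + 0.09) = 2.16
cluster_statistic <- function(gaps) {
  k <- length(gaps) - 1L
  if (k < 1) stopf("S is undefined for clusters without internal foci (k = 0)")
  if (any(gaps < 0)) stopf("gaps must be non-negative")
  if (abs(sum(gaps) - 1) > 1e-8)
    stopf("gaps must be normalised to sum to 1 (see normalize_gaps)")
  sum((gaps - 1 / (k + 1))^2) * (k + 1)^2 * (k + 2) / k
}

# coefficient of variation of the gaps, an alternative per-cluster
# regularity statistic (small = regular)
.cv_statistic <- function(gaps) {
  stats::sd(gaps) / mean(gaps)
}

#' Null distribution of the total spacing statistic
#'
#' Simulates the test statistic under the null hypothesis of no
#' interference: for each cluster with `k` internal foci, `k` independent
#' uniforms are dropped on the unit interval (the outer foci fixed at 0
#' and 1), the `k + 1` gaps formed, the per-cluster statistic computed,
#' and the statistics summed over clusters.
#'
#' @param k Integer vector of internal focus counts, one per cluster
#'   (all `>= 1`).
#' @param n_sim Number of simulated datasets (default `1e5`).
#' @param seed Optional RNG seed.
#' @param statistic `"S"` (default, see [cluster_statistic()]) or `"cv"`
#'   (sum of per-cluster gap coefficients of variation).
#' @return Numeric vector of `n_sim` simulated total statistics.
#' @details Gaps between sorted uniforms and the interval boundaries are
#'   jointly Dirichlet(1, ..., 1), so they are drawn directly as
#'   normalised exponentials.
#' @export
#' @examples
#' s0 <- simulate_null_S(k = c(1, 2), n_sim = 1000, seed = 1)
#' mean(s0) # close to (1+1) + (2+1) = 5
simulate_null_S <- function(k, n_sim = 1e5, seed = NULL,
                            statistic = c("S", "cv")) {
  statistic <- match.arg(statistic)
  if (length(k) == 0) stopf("no clusters")
  if (any(k < 1) || any(k != round(k)))
    stopf("all clusters must have at least one internal focus (k >= 1)")
  check_scalar(n_sim, "n_sim", 1, integer = TRUE)
  with_seed_or_not(seed, {
    total <- numeric(n_sim)
    for (ki in k) {
      e <- matrix(stats::rexp(n_sim * (ki + 1)), n_sim, ki + 1)
      g <- e / rowSums(e)
      total <- total + if (statistic == "S")
        rowSums((g - 1 / (ki + 1))^2) * (ki + 1)^2 * (ki + 2) / ki
      else
        apply(g, 1, .cv_statistic)
    }
    total
  })
}

#' Monte-Carlo p-value for the spacing test
#'
#' The proportion of simulated null statistics strictly smaller than the
#' observed one. Small values of S mean the foci are more evenly spaced
#' than uniform, i.e. they interfere, so small p rejects the
#' no-interference null.
#'
#' @param s_obs Observed total statistic.
#' @param null_s Simulated null sample from [simulate_null_S()].
#' @param corrected If `TRUE`, use the bias-corrected estimator
#'   `(r + 1) / (n + 1)` (never exactly zero) instead of the plain
#'   proportion.
#' @return The p-value.
#' @export
mc_pvalue <- function(s_obs, null_s, corrected = FALSE) {
  check_scalar(s_obs, "s_obs")
  if (length(null_s) == 0) stopf("empty null sample")
  r <- sum(null_s < s_obs)
  if (corrected) (r + 1) / (length(null_s) + 1) else r / length(null_s)
}

#' Monte-Carlo test of even focus spacing within clusters
#'
#' Tests whether foci inside clusters are more evenly spaced than expected
#' if they were dropped uniformly (the signature of crossover
#' interference acting within clusters). Each cluster's outermost foci
#' define its span; the statistic S measures the departure of the
#' internal gaps from equality, summed over clusters, and is compared to
#' its distribution under uniformity obtained by direct simulation with
#' the same cluster sizes.
#'
#' @param clusters A list of numeric position vectors (one per cluster),
#'   or a `"foci_clusters"` object from [detect_clusters()] (its clusters
#'   with at least `min_foci` foci are used).
#' @param n_sim Number of null simulations (default `1e5`).
#' @param seed Optional RNG seed.
#' @param statistic `"S"` (default) or `"cv"` (sum of per-cluster gap
#'   coefficients of variation), an alternative regularity measure.
#' @param min_foci Minimum foci per testable cluster (>= 3).
#' @param corrected Passed to [mc_pvalue()].
#' @return An object of class `"cluster_test"`: a list with `S_total`,
#'   `per_cluster` (data frame of sizes and statistics), `k`, `p_value`,
#'   `null_mean`, `n_sim`, `statistic` and `seed`.
#' @export
#' @examples
#' # three clusters, regularly spaced foci: small S, small p
#' cl <- list(c(0, 5, 10), c(2, 4.1, 6, 8), c(0, 3, 6.1))
#' cluster_interference_test(cl, n_sim = 2000, seed = 42)
cluster_interference_test <- function(clusters, n_sim = 1e5, seed = NULL,
                                      statistic = c("S", "cv"),
                                      min_foci = 3, corrected = FALSE) {
  statistic <- match.arg(statistic)
  if (inherits(clusters, "foci_clusters"))
    clusters <- clusters$clusters$positions
  if (!is.list(clusters) || !all(vapply(clusters, is.numeric, TRUE)))
    stopf("'clusters' must be a list of numeric position vectors")
  if (min_foci < 3) stopf("'min_foci' must be at least 3")
  n_in <- length(clusters)
  clusters <- clusters[vapply(clusters, length, 1L) >= min_foci]
  if (length(clusters) == 0)
    stopf("no testable clusters (need >= %d foci each; %d supplied)",
          min_foci, n_in)
  gaps <- lapply(clusters, normalize_gaps)
  stat_fun <- if (statistic == "S") cluster_statistic else .cv_statistic
  per <- vapply(gaps, stat_fun, 0)
  k <- vapply(gaps, length, 1L) - 1L
  s_total <- sum(per)
  null_s <- simulate_null_S(k, n_sim = n_sim, seed = seed,
                            statistic = statistic)
  structure(list(S_total = s_total,
                 per_cluster = data.frame(n_foci = k + 2L, k = k,
                                          statistic = per),
                 k = k,
                 p_value = mc_pvalue(s_total, null_s, corrected = corrected),
                 null_mean = mean(null_s),
                 n_sim = as.integer(n_sim),
                 statistic = statistic,
                 seed = seed),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Monte-Carlo spacing test (%s statistic), %d cluster(s)\n",
              x$statistic, nrow(x$per_cluster)))
  cat(sprintf("  total statistic = %.4g (null mean %.4g, %d simulations)\n",
              x$S_total, x$null_mean, x$n_sim))
  cat(sprintf("  p = %.4g  (small p: foci more evenly spaced than uniform)\n",
              x$p_value))
  invisible(x)
}
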