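#' Tetrad class counts for one marker triple
#'
#' Container for the counts of the twelve three-marker tetrad phenotype
#' classes (see [tetrad_class_table()]) observed for one ordered marker
#' triple.
#'
#' @param counts A numeric vector of twelve non-negative counts, in class
#'   order `a`-`l`. Names (`a`-`l` or `class_a`-`class_l`) are honoured
#'   if present.
#' @return An object of class `"tetrad_counts"`: a named integer vector
#'   with an `n_total` attribute.
#' @export
#' @examples
#' x <- tetrad_counts(c(a = 80, b = 10, c = 8, d = 1, e = 0, f = 0,
#'                      g = 0, h = 1, i = 0, j = 0, k = 0, l = 0))
#' interval_ptn(x, 1)
tetrad_counts <- function(counts) {
  if (length(counts) != 12L)
    stopf("'counts' must have 12 entries (classes a-l), got %d", length(counts))
  if (!is.null(names(counts))) {
    nm <- sub("^class_", "", names(counts))
    if (!setequal(nm, .tc$class))
      stopf("count names must be a-l or class_a-class_l")
    counts <- counts[match(.tc$class, nm)]
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stopf("class counts must be non-negative integers")
  out <- as.integer(counts)
  names(out) <- .tc$class
  structure(out, n_total = sum(out), class = "tetrad_counts")
}

#' @export
print.tetrad_counts <- function(x, ...) {
  cat(sprintf("Tetrad class counts (n = %d)\n", attr(x, "n_total")))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Marginal P/T/NPD counts of one marker interval
#'
#' Marginalises the twelve-class counts over the other interval, giving
#' the parental-ditype (P), tetratype (T) and nonparental-ditype (NPD)
#' counts used by [perkins_distance()] and [npd_ratio()].
#'
#' @param counts A [tetrad_counts] object (or 12-vector accepted by it).
#' @param interval 1 or 2: which of the two marker intervals.
#' @return An object of class `"interval_ptn"`: a list with elements `P`,
#'   `T`, `NPD`, `n_total` and `interval`.
#' @export
interval_ptn <- function(counts, interval = 1) {
  if (!inherits(counts, "tetrad_counts")) counts <- tetrad_counts(counts)
  if (!interval %in% c(1, 2)) stopf("'interval' must be 1 or 2")
  status <- if (interval == 1) .tc$status1 else .tc$status2
  x <- as.integer(counts)
  out <- list(P = sum(x[status == "P"]),
              T = sum(x[status == "T"]),
              NPD = sum(x[status == "NPD"]),
              n_total = sum(x), interval = as.integer(interval))
  class(out) <- "interval_ptn"
  out
}

#' @export
print.interval_ptn <- function(x, ...) {
  cat(sprintf("Interval %d: P = %d, T = %d, NPD = %d (n = %d)\n",
              x$interval, x$P, x$T, x$NPD, x$n_total))
  invisible(x)
}

#' Perkins map distance from tetrad counts
#'
#' The tetrad-based estimator of genetic distance,
#' `d(cM) = 100 * (6*NPD + T) / (2 * (P + T + NPD))`, which corrects the
#' tetratype frequency for the double crossovers revealed by NPD tetrads.
#'
#' @param P An [interval_ptn] object, or the parental-ditype count (then
#'   `T` and `NPD` must be given; all three may be vectors).
#' @param T,NPD Tetratype and nonparental-ditype counts.
#' @return Genetic distance(s) in centimorgans.
#' @export
#' @examples
#' perkins_distance(P = 50, T = 50, NPD = 0) # 25 cM
perkins_distance <- function(P, T = NULL, NPD = NULL) {
  if (inherits(P, "interval_ptn")) {
    NPD <- P$NPD; T <- P$T; P <- P$P
  }
  if (is.null(T) || is.null(NPD))
    stopf("supply an interval_ptn object or all of P, T, NPD")
  n <- P + T + NPD
  if (any(n == 0)) stopf("undefined distance: no tetrads (P + T + NPD = 0)")
  100 * (6 * NPD + T) / (2 * n)
}

#' Expected NPD frequency under no interference
#'
#' Papazian's closed form for the frequency of nonparental-ditype tetrads
#' expected from the observed tetratype frequency if double crossovers
#' occur independently (no interference, no chromatid interference):
#' `NPD_exp = (1 - T - (1 - 3*T/2)^(2/3)) / 2`.
#'
#' @param t_freq Observed tetratype frequency, in `[0, 2/3]` (the
#'   no-interference model cannot produce more than 2/3 tetratypes).
#' @return Expected NPD frequency (vectorised).
#' @export
#' @examples
#' expected_npd(0.2)
expected_npd <- function(t_freq) {
  if (any(is.na(t_freq)) || any(t_freq < 0) || any(t_freq > 2/3))
    stopf("tetratype frequency must be in [0, 2/3] under the no-interference model")
  0.5 * (1 - t_freq - (1 - 1.5 * t_freq)^(2/3))
}

# shared container for interference statistics
interference_result <- function(statistic, value, components, p_vs_1,
                                se = NA_real_, ci = c(NA_real_, NA_real_),
                                p_vs_reference = NA_real_,
                                n_resamples = 0L, seed = NULL, note = NULL) {
  structure(list(statistic = statistic, value = value,
                 components = components, p_vs_1 = p_vs_1,
                 p_vs_reference = p_vs_reference, se = se, ci = ci,
                 n_resamples = n_resamples, seed = seed, note = note),
            class = "interference_result")
}

#' @export
print.interference_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s = %s", x$statistic, format(x$value, digits = digits)))
  if (!is.na(x$se)) cat(sprintf(" (bootstrap SE %s)", format(x$se, digits = 2)))
  cat("\n")
  comp <- unlist(x$components)
  cat("  ", paste(names(comp), format(comp, digits = digits), sep = " = ",
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  p (vs 1) = %s", format.pval(x$p_vs_1, digits = 2)))
  if (!is.na(x$p_vs_reference))
    cat(sprintf(", p (vs reference) = %s", format.pval(x$p_vs_reference, digits = 2)))
  cat("\n")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' NPD ratio: intra-interval interference
#'
#' Compares the observed frequency of nonparental-ditype tetrads (the
#' product of four-strand double crossovers within one interval) with the
#' frequency expected under no interference ([expected_npd()]). An NPD
#' ratio of 1 indicates no interference, values below 1 interference
#' (down to 0, absolute interference), values above 1 negative
#' interference (an excess of closely spaced double COs).
#'
#' @param ptn An [interval_ptn] object.
#' @param n_resamples Bootstrap resamples (multinomial over P/T/NPD) used
#'   for the standard error and percentile CI of the ratio.
#' @param seed Optional RNG seed for the bootstrap.
#' @return An `interference_result` with the ratio, observed and expected
#'   NPD frequencies, an exact binomial `p_vs_1` (observed NPD count
#'   tested against the expected frequency), bootstrap `se` and 95% `ci`.
#' @export
#' @examples
#' cfg <- sim_config(nu = 1, n_tetrads = 20000, seed = 2)
#' npd_ratio(interval_ptn(simulate_tetrad_dataset(cfg), 1), seed = 2)
npd_ratio <- function(ptn, n_resamples = 10000, seed = NULL) {
  stopifnot(inherits(ptn, "interval_ptn"))
  n <- ptn$n_total
  if (n == 0) stopf("no tetrads")
  f_T <- ptn$T / n
  f_npd <- ptn$NPD / n
  if (ptn$T == 0 && ptn$NPD > 0)
    stopf("inconsistent counts: NPD tetrads without any tetratypes")
  f_exp <- expected_npd(f_T)
  if (f_exp == 0) {
    value <- if (f_npd == 0) NA_real_ else Inf
    return(interference_result("NPDr", value,
                               list(NPD_obs = f_npd, NPD_exp = f_exp),
                               p_vs_1 = NA_real_,
                               note = "expected NPD frequency is 0"))
  }
  value <- f_npd / f_exp
  p1 <- stats::binom.test(ptn$NPD, n, p = f_exp)$p.value
  boot <- with_seed_or_not(seed, {
    draws <- stats::rmultinom(n_resamples, n, c(ptn$P, ptn$T, ptn$NPD) / n)
    ft <- pmin(draws[2, ] / n, 2/3)
    fe <- expected_npd(ft)
    ifelse(fe > 0, (draws[3, ] / n) / fe, NA_real_)
  })
  boot <- boot[is.finite(boot)]
  interference_result("NPDr", value,
                      list(NPD_obs = f_npd, NPD_exp = f_exp),
                      p_vs_1 = p1,
                      se = stats::sd(boot),
                      ci = unname(stats::quantile(boot, c(0.025, 0.975))),
                      n_resamples = n_resamples, seed = seed)
}

# P/T/NPD counts of `interval` restricted to a subset of classes
.subset_ptn <- function(x, interval, classes) {
  status <- if (interval == 1) .tc$status1 else .tc$status2
  keep <- names(x) %in% classes
  c(P = sum(x[keep & status == "P"]),
    T = sum(x[keep & status == "T"]),
    NPD = sum(x[keep & status == "NPD"]))
}

# vectorised Perkins over a 12 x B matrix of class counts
.perkins_cols <- function(m, interval, classes) {
  status <- if (interval == 1) .tc$status1 else .tc$status2
  keep <- .tc$class %in% classes
  T <- colSums(m[keep & status == "T", , drop = FALSE])
  NPD <- colSums(m[keep & status == "NPD", , drop = FALSE])
  n <- colSums(m[keep, , drop = FALSE])
  ifelse(n > 0, 100 * (6 * NPD + T) / (2 * n), NA_real_)
}

#' Interference ratio between adjacent intervals
#'
#' The Malkova interference ratio (IR) compares the Perkins genetic length
#' of a target interval among tetrads that carry a crossover in the
#' adjacent interval (tetratype or NPD status there) with its length
#' among tetrads that do not. IR = 1 when crossovers in the two intervals
#' are independent; IR < 1 indicates interference, IR > 1 negative
#' interference.
#'
#' @param counts A [tetrad_counts] object for the marker triple.
#' @param target_interval 1 or 2: the interval whose length is compared.
#' @param n_resamples Bootstrap resamples (multinomial over the twelve
#'   classes) for the standard error, CI and p-values.
#' @param seed Optional RNG seed for the bootstrap.
#' @param reference Optional second [tetrad_counts] object (e.g. wild
#'   type); its IR is bootstrapped alongside to give `p_vs_reference`.
#' @return An `interference_result` with the IR, the two conditional
#'   Perkins distances (`d_with`, `d_without`, cM), two-sided percentile
#'   bootstrap `p_vs_1` (and `p_vs_reference`), `se` and 95% `ci`.
#' @export
interference_ratio <- function(counts, target_interval = 1,
                               n_resamples = 10000, seed = NULL,
                               reference = NULL) {
  if (!inherits(counts, "tetrad_counts")) counts <- tetrad_counts(counts)
  if (!target_interval %in% c(1, 2)) stopf("'target_interval' must be 1 or 2")
  adjacent <- 3L - as.integer(target_interval)
  adj_status <- if (adjacent == 1) .tc$status1 else .tc$status2
  with_co <- .tc$class[adj_status != "P"]
  without <- .tc$class[adj_status == "P"]
  x <- stats::setNames(as.integer(counts), names(counts))
  ir_point <- .ir_from_counts(x, target_interval, with_co, without,
                              error = TRUE)
  boot <- ref_boot <- NULL
  if (n_resamples > 0) {
    boot <- with_seed_or_not(seed, {
      b <- stats::rmultinom(n_resamples, sum(x), x / sum(x))
      ir <- .perkins_cols(b, target_interval, with_co) /
        .perkins_cols(b, target_interval, without)
      if (!is.null(reference)) {
        if (!inherits(reference, "tetrad_counts"))
          reference <- tetrad_counts(reference)
        r <- as.integer(reference)
        rb <- stats::rmultinom(n_resamples, sum(r), r / sum(r))
        ref_boot <- .perkins_cols(rb, target_interval, with_co) /
          .perkins_cols(rb, target_interval, without)
      }
      ir
    })
  }
  ok <- is.finite(boot)
  p1 <- if (any(ok)) min(1, 2 * min(mean(boot[ok] <= 1), mean(boot[ok] >= 1)))
        else NA_real_
  pref <- NA_real_
  if (!is.null(ref_boot)) {
    d <- boot - ref_boot
    d <- d[is.finite(d)]
    pref <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  }
  interference_result("IR", ir_point$ir,
                      list(d_with = ir_point$d_with,
                           d_without = ir_point$d_without),
                      p_vs_1 = p1, p_vs_reference = pref,
                      se = if (any(ok)) stats::sd(boot[ok]) else NA_real_,
                      ci = if (any(ok))
                        unname(stats::quantile(boot[ok], c(0.025, 0.975)))
                      else c(NA_real_, NA_real_),
                      n_resamples = n_resamples, seed = seed)
}

.ir_from_counts <- function(x, interval, with_co, without, error = FALSE) {
  a <- .subset_ptn(x, interval, with_co)
  b <- .subset_ptn(x, interval, without)
  if (sum(a) == 0 || sum(b) == 0) {
    if (error)
      stopf("undefined IR: %s tetrads %s a crossover in the adjacent interval",
            if (sum(a) == 0) "no" else "only",
            if (sum(a) == 0) "carry" else "lack")
    return(list(ir = NA_real_, d_with = NA_real_, d_without = NA_real_))
  }
  d_with <- perkins_distance(a[["P"]], a[["T"]], a[["NPD"]])
  d_without <- perkins_distance(b[["P"]], b[["T"]], b[["NPD"]])
  if (d_without == 0) {
    if (error) stopf("undefined IR: zero map length without adjacent crossover")
    return(list(ir = NA_real_, d_with = d_with, d_without = d_without))
  }
  list(ir = d_with / d_without, d_with = d_with, d_without = d_without)
}

#' Coefficient of coincidence of two adjacent intervals
#'
#' Compares the observed frequency of tetrads carrying a crossover in both
#' intervals (tetratype or NPD status in each) with the product of the
#' single-interval crossover frequencies. A value of 1 indicates no
#' interference, 0 total interference, values above 1 an excess of double
#' crossovers.
#'
#' @inheritParams interference_ratio
#' @return An `interference_result` with the c.o.c., the component
#'   frequencies (`f_obs`, `f_exp`), bootstrap `se`, 95% `ci` and
#'   two-sided percentile `p_vs_1`.
#' @export
coefficient_of_coincidence <- function(counts, n_resamples = 10000,
                                       seed = NULL) {
  if (!inherits(counts, "tetrad_counts")) counts <- tetrad_counts(counts)
  x <- as.integer(counts)
  n <- sum(x)
  if (n == 0) stopf("no tetrads")
  co1 <- .tc$status1 != "P"
  co2 <- .tc$status2 != "P"
  f_a <- sum(x[co1]) / n
  f_b <- sum(x[co2]) / n
  if (f_a == 0 || f_b == 0)
    stopf("undefined c.o.c.: no crossovers observed in interval %s",
          if (f_a == 0) "1" else "2")
  f_obs <- sum(x[co1 & co2]) / n
  f_exp <- f_a * f_b
  boot <- with_seed_or_not(seed, {
    b <- stats::rmultinom(n_resamples, n, x / n)
    ba <- colSums(b[co1, , drop = FALSE]) / n
    bb <- colSums(b[co2, , drop = FALSE]) / n
    bab <- colSums(b[co1 & co2, , drop = FALSE]) / n
    ifelse(ba > 0 & bb > 0, bab / (ba * bb), NA_real_)
  })
  ok <- is.finite(boot)
  interference_result("c.o.c.", f_obs / f_exp,
                      list(f_obs = f_obs, f_exp = f_exp),
                      p_vs_1 = if (any(ok))
                        min(1, 2 * min(mean(boot[ok] <= 1), mean(boot[ok] >= 1)))
                      else NA_real_,
                      se = stats::sd(boot[ok]),
                      ci = unname(stats::quantile(boot[ok], c(0.025, 0.975))),
                      n_resamples = n_resamples, seed = seed)
}
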