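# hand-built tetrads (rows = spores, cols = markers in map order)
tetrad_pd <- function() rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))

tetrad_t1 <- function() rbind(c(1, 1, 1), c(1, 0, 0), c(0, 1, 1), c(0, 0, 0))

tetrad_npd1 <- function() rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 1), c(0, 1, 1))

# all 4-spore x 3-marker 0/1 matrices with 2:2 segregation at every marker
all_viable_tetrads <- function() {
  pair_patterns <- apply(utils::combn(4, 2), 2, function(j) {
    v <- integer(4); v[j] <- 1L; v
  })
  out <- list()
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    out[[length(out) + 1]] <- cbind(pair_patterns[, i], pair_patterns[, j],
                                    pair_patterns[, k])
  out
}

# textbook P/T/NPD status of one interval, computed directly from the
# two-marker haplotype multiset (independent of the class table)
interval_status_oracle <- function(spores, interval) {
  h <- spores[, interval] * 2 + spores[, interval + 1]
  parental <- sum(h %in% c(3, 0))
  if (parental == 4) "P" else if (parental == 0) "NPD" else "T"
}

# class counts with given entries, rest zero
counts_of <- function(...) {
  x <- stats::setNames(integer(12), letters[1:12])
  spec <- c(...)
  x[names(spec)] <- spec
  tetrad_counts(x)
}
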