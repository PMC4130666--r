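#' The twelve three-marker tetrad phenotype classes
#'
#' A tetrad scored for three ordered linked markers, with every marker
#' segregating 2:2, can display exactly twelve distinct multisets of spore
#' phenotypes. Each multiset is one phenotype class, labelled `a`-`l`:
#'
#' | class | interval 1 | interval 2 | note |
#' |-------|------------|------------|------|
#' | a | P   | P   | parental ditype, no visible CO |
#' | b | T   | P   | single CO, interval 1 |
#' | c | P   | T   | single CO, interval 2 |
#' | d | T   | T   | two-strand double (both parental spores retained) |
#' | e | T   | T   | three-strand double (triple-marked parental retained) |
#' | f | T   | T   | three-strand double (unmarked parental retained) |
#' | g | T   | T   | four-strand double (no parental spore) |
#' | h | NPD | P   | |
#' | i | NPD | T   | |
#' | j | T   | NPD | |
#' | k | P   | NPD | |
#' | l | NPD | NPD | |
#'
#' Classes `h`-`l` are exactly those containing a nonparental-ditype (NPD)
#' pattern in at least one interval; NPDs arise from four-strand double COs
#' within a single interval. `tetrad_class_table()` returns this mapping as
#' a data frame; the interval status columns drive every downstream
#' statistic ([interval_ptn()], [interference_ratio()],
#' [coefficient_of_coincidence()]).
#'
#' @return A data frame with one row per class: `class`, `status1`,
#'   `status2` (each `"P"`, `"T"` or `"NPD"`), and `spores`, the canonical
#'   phenotype multiset written as four triples of 0/1 marker presences.
#' @seealso [classify_tetrad()]
#' @export
#' @examples
#' tetrad_class_table()
tetrad_class_table <- function() {
  data.frame(
    class = .tc$class,
    status1 = .tc$status1,
    status2 = .tc$status2,
    spores = vapply(.tc$codes, function(v)
      paste(vapply(v, .code_to_string, ""), collapse = " "), ""),
    stringsAsFactors = FALSE
  )
}

# Canonical class definitions. A spore phenotype over the ordered markers
# (m1, m2, m3) is encoded as 4*m1 + 2*m2 + m3; a tetrad is the ascending
# sorted vector of its four spore codes. Homolog carrying the markers = 7
# (all present), the other homolog = 0.
.tc <- local({
  codes <- list(
    a = c(0, 0, 7, 7), # {111,111,000,000}
    b = c(0, 3, 4, 7), # {111,011,100,000}
    c = c(0, 1, 6, 7), # {111,110,001,000}
    d = c(0, 2, 5, 7), # {111,101,010,000}
    e = c(1, 2, 4, 7), # {111,100,010,001}
    f = c(0, 3, 5, 6), # {110,101,011,000}
    g = c(1, 3, 4, 6), # {110,100,011,001}
    h = c(3, 3, 4, 4), # {100,100,011,011}
    i = c(2, 3, 4, 5), # {101,100,011,010}
    j = c(1, 2, 5, 6), # {110,101,010,001}
    k = c(1, 1, 6, 6), # {110,110,001,001}
    l = c(2, 2, 5, 5)  # {101,101,010,010}
  )
  list(
    class = names(codes),
    codes = codes,
    key = vapply(codes, function(v) ((v[1] * 8 + v[2]) * 8 + v[3]) * 8 + v[4], 0),
    status1 = c(a = "P", b = "T", c = "P", d = "T", e = "T", f = "T",
                g = "T", h = "NPD", i = "NPD", j = "T", k = "P", l = "NPD"),
    status2 = c(a = "P", b = "P", c = "T", d = "T", e = "T", f = "T",
                g = "T", h = "P", i = "T", j = "NPD", k = "NPD", l = "NPD")
  )
})

.code_to_string <- function(code) {
  paste0(code %/% 4, (code %/% 2) %% 2, code %% 2)
}

# key of a sorted 4-vector of spore codes
.tetrad_key <- function(v) ((v[1] * 8 + v[2]) * 8 + v[3]) * 8 + v[4]

#' Classify a three-marker tetrad
#'
#' Assigns a four-spore tetrad to one of the twelve phenotype classes
#' (see [tetrad_class_table()]) and reports the parental/tetratype/NPD
#' status of each of the two marker intervals.
#'
#' @param spores A 4 x 3 matrix (rows = spores, columns = markers in map
#'   order) of 0/1 or logical marker presences.
#' @return A list with `class` (one of `"a"`-`"l"`), and `status`, a named
#'   character vector giving the `"P"`/`"T"`/`"NPD"` status of
#'   `interval1` and `interval2`.
#' @details Tetrads in which any marker does not segregate 2:2 (a scoring
#'   error, or spore death upstream) are rejected with an error; mirror the
#'   usual practice of analysing only four-spore viable tetrads.
#' @export
#' @examples
#' pd <- rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 0), c(0, 0, 0))
#' classify_tetrad(pd) # class "a": parental ditype
classify_tetrad <- function(spores) {
  spores <- as.matrix(spores)
  if (!all(dim(spores) == c(4L, 3L)))
    stopf("'spores' must be a 4 x 3 matrix (4 spores x 3 markers)")
  if (is.logical(spores)) spores <- spores * 1L
  if (!all(spores %in% c(0, 1)))
    stopf("marker presences must be 0/1 or logical")
  if (!all(colSums(spores) == 2))
    stopf("malformed tetrad: every marker must segregate 2:2 (column sums %s)",
          paste(colSums(spores), collapse = ":"))
  code <- sort(spores[, 1] * 4 + spores[, 2] * 2 + spores[, 3])
  cls <- .tc$class[match(.tetrad_key(code), .tc$key)]
  # every 2:2 multiset is one of the twelve; match cannot fail
  list(class = cls,
       status = c(interval1 = unname(.tc$status1[cls]),
                  interval2 = unname(.tc$status2[cls])))
}

# vectorised classifier: `codes` is an n x 4 matrix of row-sorted spore
# phenotype codes; returns factor of class letters
.classify_keys <- function(codes) {
  key <- ((codes[, 1] * 8 + codes[, 2]) * 8 + codes[, 3]) * 8 + codes[, 4]
  factor(.tc$class[match(key, .tc$key)], levels = .tc$class)
}
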