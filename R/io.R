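#' Read a tetrad table
#'
#' Reads tab-delimited tetrad data in either of two dialects:
#' * **wide** — one row per dataset with columns `class_a` ... `class_l`
#'   (extra identifier columns are kept as the dataset name);
#' * **long** — one row per spore with columns `tetrad_id`, `spore_id`,
#'   `marker1`, `marker2`, `marker3` (0/1 presences); tetrads are
#'   classified with [classify_tetrad()]. Tetrads without exactly four
#'   spores or without 2:2 segregation at every marker (inviable or
#'   mis-scored) are dropped with a message; the tally is recorded in
#'   `attr(, "n_dropped")`.
#'
#' @param path Path to a TSV file (header row, UTF-8).
#' @param format `"auto"` (default; sniffed from the header), `"wide"` or
#'   `"long"`.
#' @return A [tetrad_counts] object, or a named list of them when a wide
#'   file holds several rows.
#' @export
read_tetrad_table <- function(path, format = c("auto", "wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  wide_cols <- paste0("class_", .tc$class)
  if (format == "auto")
    format <- if (all(wide_cols %in% names(d))) "wide" else "long"
  if (format == "wide") {
    unknown <- setdiff(grep("^class_", names(d), value = TRUE), wide_cols)
    if (length(unknown))
      stopf("unknown tetrad class column(s): %s", paste(unknown, collapse = ", "))
    if (!all(wide_cols %in% names(d)))
      stopf("wide tetrad table must have columns %s",
            paste(wide_cols, collapse = ", "))
    id_col <- setdiff(names(d), wide_cols)[1]
    out <- lapply(seq_len(nrow(d)), function(i) {
      row <- as.numeric(d[i, wide_cols])
      bad <- which(is.na(row) | row < 0 | row != round(row))
      if (length(bad))
        stopf("row %d, column %s: counts must be non-negative integers",
              i, wide_cols[bad[1]])
      tetrad_counts(stats::setNames(row, wide_cols))
    })
    if (length(out) == 1L) return(out[[1]])
    names(out) <- if (!is.na(id_col)) as.character(d[[id_col]]) else
      paste0("dataset", seq_along(out))
    return(out)
  }
  need <- c("tetrad_id", "spore_id", "marker1", "marker2", "marker3")
  if (!all(need %in% names(d)))
    stopf("long tetrad table must have columns %s", paste(need, collapse = ", "))
  mk <- as.matrix(d[, c("marker1", "marker2", "marker3")])
  if (!all(mk %in% c(0, 1)))
    stopf("marker presences must be 0/1 in the long dialect")
  counts <- stats::setNames(integer(12), .tc$class)
  dropped <- 0L
  for (id in unique(d$tetrad_id)) {
    sp <- mk[d$tetrad_id == id, , drop = FALSE]
    cls <- if (nrow(sp) == 4L && all(colSums(sp) == 2))
      classify_tetrad(sp)$class else NA_character_
    if (is.na(cls)) dropped <- dropped + 1L
    else counts[cls] <- counts[cls] + 1L
  }
  if (dropped > 0)
    message(sprintf("dropped %d tetrad(s) without four 2:2-segregating spores",
                    dropped))
  out <- tetrad_counts(counts)
  attr(out, "n_dropped") <- dropped
  out
}

#' Write tetrad class counts as a wide TSV
#'
#' @param counts A [tetrad_counts] object or a named list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tetrad_table <- function(counts, path) {
  if (inherits(counts, "tetrad_counts")) counts <- list(dataset1 = counts)
  rows <- lapply(counts, function(x)
    as.data.frame(as.list(stats::setNames(as.integer(x),
                                          paste0("class_", names(x))))))
  d <- cbind(dataset = names(counts), do.call(rbind, rows))
  rownames(d) <- NULL
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a foci table
#'
#' Foci tables are TSV files with one row per focus: `cell_id`,
#' `axis_id`, `position_um`, `axis_length_um`.
#'
#' @param path File path.
#' @return `read_foci_table()` returns the validated data frame;
#'   `write_foci_table()` returns `path` invisibly.
#' @export
read_foci_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "axis_id", "position_um", "axis_length_um")
  if (!all(need %in% names(d)))
    stopf("foci table must have columns %s", paste(need, collapse = ", "))
  if (any(d$axis_length_um <= 0)) stopf("axis lengths must be positive")
  bad <- which(d$position_um < 0 | d$position_um > d$axis_length_um)
  if (length(bad))
    stopf("row %d: focus position outside [0, axis length]", bad[1])
  d
}

#' @rdname read_foci_table
#' @param foci A foci data frame (e.g. from [simulate_foci_cells()]).
#' @export
write_foci_table <- function(foci, path) {
  utils::write.table(foci, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metaphase table
#'
#' TSV with one row per cell: `cell_id`, `n_ring`, `n_rod`,
#' `n_univalent_pairs`.
#'
#' @param path File path.
#' @param n_pairs Expected homolog pair number per cell (validation).
#' @return The validated data frame.
#' @export
read_metaphase_table <- function(path, n_pairs = 5) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_metaphase(d, n_pairs)
  d
}
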