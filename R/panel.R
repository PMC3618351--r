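#' Construct a marker panel
#'
#' A marker panel is the ordered physical map of the SNPs genotyped in a
#' backcross: for every marker its autosome (1-19), physical position in bp
#' and an identifier, together with the physical size of each autosome.
#' Consecutive retained markers on the same chromosome define the intervals
#' in which crossovers are detectable.
#'
#' @param markers data frame with columns `chrom` (integer autosome id),
#'   `pos_bp` (1-based physical position in bp) and `marker_id` (unique
#'   string).  Rows may be in any order; they are sorted by `(chrom, pos_bp)`.
#' @param chrom_sizes named numeric vector, chromosome size in Mbp, names are
#'   autosome ids.  Every chromosome present in `markers` must be listed.
#' @return An object of class `marker_panel`: a list with the sorted
#'   `markers` data frame and `chrom_sizes`.
#' @details Invariants enforced: positions are unique within a chromosome,
#'   every position lies inside its chromosome, and any chromosome carrying
#'   markers carries at least two of them (a single marker defines no
#'   interval and cannot reveal a crossover).
#' @seealso [read_panel()], [summarize_panel()], [panel_intervals()]
#' @export
marker_panel <- function(markers, chrom_sizes) {
  if (!is.data.frame(markers) ||
      !all(c("chrom", "pos_bp", "marker_id") %in% names(markers)))
    xo_abort("`markers` must have columns chrom, pos_bp, marker_id")
  markers <- data.frame(chrom = as.integer(markers$chrom),
                        pos_bp = as.numeric(markers$pos_bp),
                        marker_id = as.character(markers$marker_id),
                        stringsAsFactors = FALSE)
  if (anyNA(markers$chrom) || anyNA(markers$pos_bp))
    xo_abort_format("non-numeric chromosome or position in marker table")
  if (any(markers$pos_bp <= 0))
    xo_abort_format("marker positions must be positive (1-based bp)")
  if (anyDuplicated(markers$marker_id))
    xo_abort_format(sprintf("duplicate marker id: %s",
                            markers$marker_id[duplicated(markers$marker_id)][1]))
  markers <- markers[order(markers$chrom, markers$pos_bp), , drop = FALSE]
  rownames(markers) <- NULL

  dup <- duplicated(markers[, c("chrom", "pos_bp")])
  if (any(dup))
    xo_abort_format(sprintf(
      "duplicate position: chrom %d pos %d (markers %s)",
      markers$chrom[dup][1], markers$pos_bp[dup][1],
      paste(markers$marker_id[markers$chrom == markers$chrom[dup][1] &
                              markers$pos_bp == markers$pos_bp[dup][1]],
            collapse = ", ")))

  if (is.null(names(chrom_sizes)))
    xo_abort("`chrom_sizes` must be a named vector (autosome id -> Mbp)")
  sizes <- as.numeric(chrom_sizes)
  names(sizes) <- names(chrom_sizes)

  missing_chr <- setdiff(unique(markers$chrom), as.integer(names(sizes)))
  if (length(missing_chr))
    xo_abort_format(sprintf("unknown chromosome in marker table: %s",
                            paste(missing_chr, collapse = ", ")))
  over <- markers$pos_bp > sizes[as.character(markers$chrom)] * 1e6
  if (any(over))
    xo_abort_format(sprintf("marker %s at %g bp exceeds chromosome %d size",
                            markers$marker_id[over][1],
                            markers$pos_bp[over][1], markers$chrom[over][1]))
  singles <- names(which(table(markers$chrom) < 2))
  if (length(singles))
    xo_abort_format(sprintf(
      "chromosome(s) %s carry a single marker; at least two are required",
      paste(singles, collapse = ", ")))

  structure(list(markers = markers, chrom_sizes = sizes),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  n_chr <- length(unique(x$markers$chrom))
  cat(sprintf("<marker_panel> %d markers on %d autosomes (%d intervals)\n",
              nrow(x$markers), n_chr, nrow(x$markers) - n_chr))
  invisible(x)
}

#' Read a marker panel from TSV files
#'
#' @param path TSV with header columns `chrom`, `pos_bp`, `marker_id`.
#' @param chrom_sizes either a named numeric vector (Mbp) or the path of a
#'   companion TSV with columns `chrom`, `size_mbp`.
#' @return A validated [marker_panel()].
#' @export
read_panel <- function(path, chrom_sizes) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos_bp", "marker_id")
  if (!all(need %in% names(tab)))
    xo_abort_format(sprintf("%s: missing column(s) %s", path,
                            paste(setdiff(need, names(tab)), collapse = ", ")))
  chrom <- suppressWarnings(as.integer(tab$chrom))
  pos <- suppressWarnings(as.numeric(tab$pos_bp))
  bad <- which(is.na(chrom) | is.na(pos))
  if (length(bad))
    xo_abort_format(sprintf("%s: non-numeric chrom/pos at data line %d",
                            path, bad[1]))
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L) {
    st <- utils::read.delim(chrom_sizes, stringsAsFactors = FALSE)
    if (!all(c("chrom", "size_mbp") %in% names(st)))
      xo_abort_format(sprintf("%s: expected columns chrom, size_mbp",
                              chrom_sizes))
    chrom_sizes <- stats::setNames(as.numeric(st$size_mbp),
                                   as.character(st$chrom))
  }
  marker_panel(data.frame(chrom = chrom, pos_bp = pos,
                          marker_id = tab$marker_id,
                          stringsAsFactors = FALSE),
               chrom_sizes)
}

#' Write a marker panel to TSV
#'
#' Emits the marker table and, optionally, the chromosome-size companion
#' table in the dialect accepted by [read_panel()].
#'
#' @param panel a [marker_panel()].
#' @param path destination TSV for the marker table.
#' @param sizes_path optional destination for the chrom-sizes table.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, sizes_path = NULL) {
  utils::write.table(panel$markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sizes_path)) {
    utils::write.table(
      data.frame(chrom = names(panel$chrom_sizes),
                 size_mbp = unname(panel$chrom_sizes)),
      sizes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Intervals between consecutive markers
#'
#' @param panel a [marker_panel()].
#' @return Data frame with one row per interval between consecutive markers
#'   on the same chromosome: `chrom`, `left_marker`, `right_marker`,
#'   `left_pos`, `right_pos` (bp) and `span_mbp`.
#' @export
panel_intervals <- function(panel) {
  m <- panel$markers
  keep <- which(diff(m$chrom) == 0L)  # consecutive rows on the same chrom
  data.frame(
    chrom = m$chrom[keep],
    left_marker = m$marker_id[keep],
    right_marker = m$marker_id[keep + 1L],
    left_pos = m$pos_bp[keep],
    right_pos = m$pos_bp[keep + 1L],
    span_mbp = (m$pos_bp[keep + 1L] - m$pos_bp[keep]) / 1e6,
    stringsAsFactors = FALSE)
}

#' Restrict a panel to a subset of markers
#'
#' Used after marker QC: chromosomes left with fewer than two retained
#' markers are dropped entirely (they define no interval).
#'
#' @param panel a [marker_panel()].
#' @param marker_ids markers to keep.
#' @return A list with the reduced `panel` and `dropped_chroms`, the ids of
#'   chromosomes removed because a single marker survived.
#' @export
subset_panel <- function(panel, marker_ids) {
  m <- panel$markers[panel$markers$marker_id %in% marker_ids, , drop = FALSE]
  tab <- table(m$chrom)
  drop_chr <- as.integer(names(tab)[tab < 2])
  m <- m[!(m$chrom %in% drop_chr), , drop = FALSE]
  if (nrow(m) == 0L) xo_abort("no chromosome retains two markers after subsetting")
  list(panel = marker_panel(m, panel$chrom_sizes), dropped_chroms = drop_chr)
}

#' Panel geometry summary
#'
#' Per-chromosome marker counts, inter-marker distances and physical length
#' (first-to-last marker), plus genome-wide aggregates.  The genome mean
#' inter-marker distance is total physical length divided by the number of
#' intervals; the mean of the per-chromosome maximal distances is the
#' "resolution power" of the panel (the worst-case spacing a typical
#' chromosome exposes).
#'
#' @param panel a [marker_panel()].
#' @return A list of class `panel_summary` with elements `per_chrom` (data
#'   frame: `chrom`, `size_mbp`, `n_markers`, `mean_dist`, `min_dist`,
#'   `max_dist`, `length_mbp`, all distances in Mbp) and `genome` (list:
#'   `n_markers`, `n_intervals`, `total_length_mbp`, `mean_dist`,
#'   `mean_min_dist`, `mean_max_dist`).  Full precision is kept; round for
#'   display.
#' @export
summarize_panel <- function(panel) {
  iv <- panel_intervals(panel)
  chroms <- sort(unique(panel$markers$chrom))
  per <- do.call(rbind, lapply(chroms, function(ch) {
    sp <- iv$span_mbp[iv$chrom == ch]
    data.frame(chrom = ch,
               size_mbp = unname(panel$chrom_sizes[as.character(ch)]),
               n_markers = sum(panel$markers$chrom == ch),
               mean_dist = mean(sp), min_dist = min(sp), max_dist = max(sp),
               length_mbp = sum(sp))
  }))
  rownames(per) <- NULL
  genome <- list(
    n_markers = nrow(panel$markers),
    n_intervals = nrow(iv),
    total_length_mbp = sum(per$length_mbp),
    mean_dist = sum(per$length_mbp) / nrow(iv),
    mean_min_dist = mean(per$min_dist),
    mean_max_dist = mean(per$max_dist))
  structure(list(per_chrom = per, genome = genome), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  per <- x$per_chrom
  per[c("mean_dist", "min_dist", "max_dist", "length_mbp")] <-
    lapply(per[c("mean_dist", "min_dist", "max_dist", "length_mbp")],
           round, digits = 2)
  print(per, row.names = FALSE)
  g <- x$genome
  cat(sprintf(
    "markers %d  intervals %d  length %.1f Mbp  mean gap %.2f Mbp  resolution %.2f Mbp\n",
    g$n_markers, g$n_intervals, g$total_length_mbp, g$mean_dist,
    g$mean_max_dist))
  invisible(x)
}
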