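# Crossover calling: a recombination event is a change of genotype state
# (homozygous C57BL/6J <-> heterozygous) between two consecutive retained
# SNPs on the same chromosome.  An interval can reveal at most one event
# per meiosis: an even number of true crossovers inside it cancels out.

#' Call crossover events
#'
#' Scans every sample's retained calls in positional order, chromosome by
#' chromosome, and emits one event per consecutive-marker interval whose
#' flanking states differ.  Missing calls (possible when the conservative
#' scenario left `N` cells in place) widen the comparison to the nearest
#' non-missing flanks: if those flanks differ, the single event is assigned
#' to the first interval of the gap and the remaining gap intervals are
#' marked not-assessed (`NA`); if they agree, every gap interval is
#' not-assessed and no event is called.
#'
#' @param gm a QC'd, scenario-applied [genotype_matrix()] (see [run_qc()]).
#' @param panel the matching retained [marker_panel()].
#' @return Object of class `crossover_calls`: list with
#'   `events` (samples x intervals integer matrix, 0/1/`NA`),
#'   `intervals` (as [panel_intervals()]), `samples`,
#'   `per_sample_total` (row sums, `NA`-robust), and `scenario`.
#' @export
call_events <- function(gm, panel) {
  if (!identical(colnames(gm$calls), panel$markers$marker_id))
    xo_abort("genotypes are not aligned to `panel`")
  iv <- panel_intervals(panel)
  n <- nrow(gm$calls)
  events <- matrix(NA_integer_, n, nrow(iv),
                   dimnames = list(gm$samples$sample_id,
                                   paste(iv$left_marker, iv$right_marker,
                                         sep = "..")))
  chrom_of <- panel$markers$chrom
  # interval k sits between marker columns left_idx[k] and left_idx[k] + 1
  left_idx <- match(iv$left_marker, panel$markers$marker_id)
  for (ch in unique(chrom_of)) {
    jj <- which(chrom_of == ch)                 # marker columns of this chrom
    kk <- which(iv$chrom == ch)                 # interval columns
    sub <- gm$calls[, jj, drop = FALSE]
    for (i in seq_len(n)) {
      row <- sub[i, ]
      obs <- which(row != "N")
      if (length(obs) < 2) next                 # unresolvable chromosome
      ev <- row[obs][-1] != row[obs][-length(obs)]
      for (g in seq_along(ev)) {
        from <- obs[g]; to <- obs[g + 1]
        local_iv <- kk[from:(to - 1)]           # intervals spanned by the gap
        if (to == from + 1) {
          events[i, local_iv] <- as.integer(ev[g])
        } else if (ev[g]) {
          events[i, local_iv[1]] <- 1L          # event assigned to first gap interval
        }                                       # flanks equal: all stay NA
      }
    }
  }
  structure(list(events = events, intervals = iv, samples = gm$samples,
                 per_sample_total = rowSums(events, na.rm = TRUE),
                 scenario = attr(gm, "scenario") %||% "conservative"),
            class = "crossover_calls")
}

#' @export
print.crossover_calls <- function(x, ...) {
  cat(sprintf("<crossover_calls> %d samples x %d intervals, %d events (%s scenario)\n",
              nrow(x$events), ncol(x$events), sum(x$per_sample_total),
              x$scenario))
  invisible(x)
}

#' Per-interval event totals by group
#'
#' @param calls a [call_events()] result.
#' @return Data frame: the interval table plus, per group, `x_<grp>`
#'   (events) and `n_<grp>` (assessed samples, i.e. non-`NA` cells).
#' @export
interval_totals <- function(calls) {
  out <- calls$intervals
  for (g in intersect(group_codes(), unique(calls$samples$group))) {
    rows <- calls$samples$group == g
    out[[paste0("x_", g)]] <- colSums(calls$events[rows, , drop = FALSE],
                                      na.rm = TRUE)
    out[[paste0("n_", g)]] <- colSums(!is.na(calls$events[rows, , drop = FALSE]))
  }
  out
}

#' Build a call set from published per-chromosome counts
#'
#' Wraps a table of per-chromosome event counts (such as
#' [ref_event_counts()]) into a minimal object that [chrom_stats()],
#' [group_means()] and [size_vs_rate()] accept when per-sample detail is
#' unavailable.
#'
#' @param counts data frame with column `chrom` and one column of event
#'   counts per group.
#' @param group_sizes named vector of samples per group.
#' @return Object of class `crossover_counts`.
#' @export
callset_from_counts <- function(counts, group_sizes = ref_group_sizes()) {
  if (!"chrom" %in% names(counts)) xo_abort("`counts` needs a chrom column")
  grps <- setdiff(names(counts), "chrom")
  bad <- setdiff(grps, group_codes())
  if (length(bad)) xo_abort(sprintf("unknown group column: %s", bad[1]))
  if (!all(grps %in% names(group_sizes)))
    xo_abort("`group_sizes` must cover every group column")
  structure(list(counts = counts, group_sizes = group_sizes[grps]),
            class = "crossover_counts")
}

#' Per-chromosome genetic-map statistics
#'
#' For each group and chromosome: the event count, the number of samples,
#' the genetic length `cM = 100 * count / n` (1 cM = 1% recombinants per
#' meiosis) and the map density `cM/Mbp`, dividing by the physical length
#' between the first and last retained marker.
#'
#' @param calls a `crossover_calls` ([call_events()]) or
#'   `crossover_counts` ([callset_from_counts()]) object.
#' @param panel the retained [marker_panel()] (provides the physical
#'   lengths).
#' @return Data frame with columns `chrom`, `length_mbp`, then per group
#'   `x_<grp>`, `cM_<grp>`, `cM_per_mbp_<grp>`.  Full precision; round to
#'   2 decimals for display.
#' @export
chrom_stats <- function(calls, panel) UseMethod("chrom_stats")

chrom_lengths <- function(panel) {
  s <- summarize_panel(panel)
  stats::setNames(s$per_chrom$length_mbp, s$per_chrom$chrom)
}

chrom_stats_table <- function(chrom, counts_by_group, n_by_group, panel) {
  len <- chrom_lengths(panel)
  if (!all(as.character(chrom) %in% names(len)))
    xo_abort("counts reference chromosomes absent from `panel`")
  out <- data.frame(chrom = chrom,
                    length_mbp = unname(len[as.character(chrom)]))
  for (g in names(counts_by_group)) {
    n <- n_by_group[[g]]
    if (is.na(n) || n == 0) xo_abort(sprintf("group %s has no samples", g))
    cm <- 100 * counts_by_group[[g]] / n
    out[[paste0("x_", g)]] <- counts_by_group[[g]]
    out[[paste0("n_", g)]] <- n
    out[[paste0("cM_", g)]] <- cm
    out[[paste0("cM_per_mbp_", g)]] <- cm / out$length_mbp
  }
  out
}

#' @export
chrom_stats.crossover_counts <- function(calls, panel) {
  grps <- setdiff(names(calls$counts), "chrom")
  chrom_stats_table(calls$counts$chrom,
                    calls$counts[grps],
                    as.list(calls$group_sizes),
                    panel)
}

#' @export
chrom_stats.crossover_calls <- function(calls, panel) {
  iv <- calls$intervals
  chroms <- unique(iv$chrom)
  grps <- intersect(group_codes(), unique(calls$samples$group))
  counts <- lapply(stats::setNames(grps, grps), function(g) {
    rows <- calls$samples$group == g
    vapply(chroms, function(ch)
      as.numeric(sum(calls$events[rows, iv$chrom == ch, drop = FALSE],
                     na.rm = TRUE)), 0)
  })
  ns <- lapply(stats::setNames(grps, grps),
               function(g) sum(calls$samples$group == g))
  chrom_stats_table(chroms, counts, ns, panel)
}

#' Per-group mean events per meiosis
#'
#' @param calls a `crossover_calls` or `crossover_counts` object.
#' @return Data frame with one row per group: `group`, `n`, `total`,
#'   `mean` (events per meiosis) and `sem` (standard error of the mean;
#'   `NA` when per-sample totals are unavailable or `n < 2`).
#' @export
group_means <- function(calls) UseMethod("group_means")

#' @export
group_means.crossover_calls <- function(calls) {
  grps <- intersect(group_codes(), unique(calls$samples$group))
  do.call(rbind, lapply(grps, function(g) {
    tot <- calls$per_sample_total[calls$samples$group == g]
    data.frame(group = g, n = length(tot), total = sum(tot),
               mean = mean(tot),
               sem = if (length(tot) >= 2) stats::sd(tot) / sqrt(length(tot))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' @export
group_means.crossover_counts <- function(calls) {
  grps <- setdiff(names(calls$counts), "chrom")
  do.call(rbind, lapply(grps, function(g) {
    n <- calls$group_sizes[[g]]
    tot <- sum(calls$counts[[g]])
    data.frame(group = g, n = n, total = tot, mean = tot / n,
               sem = NA_real_, stringsAsFactors = FALSE)
  }))
}

#' Sex-averaged events per meiosis
#'
#' Unweighted mean of two per-meiosis group means (the female- and
#' male-parent groups of one genotype).
#'
#' @param mean_a,mean_b two group means (events per meiosis).
#' @return Single number.
#' @export
sex_averaged <- function(mean_a, mean_b) (mean_a + mean_b) / 2
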