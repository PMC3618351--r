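#' Mann-Whitney comparison of two groups with Bonferroni correction
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test using the normal
#' approximation with tie and continuity corrections; an exact-permutation
#' variant is available for small samples.  Significance is declared at
#' `alpha / family_size` (Bonferroni).
#'
#' @param a,b numeric vectors (e.g. per-sample event totals of two groups).
#' @param family_size number of tests in the Bonferroni family (default 1).
#' @param alpha family-wise error rate (default 0.05).
#' @param exact use the exact distribution (no ties only; default `FALSE`).
#' @param name,groups labels stored in the result.
#' @return Data frame of class `xo_comparison`: `test`, `groups`,
#'   `statistic` (the U statistic of `a`), `p`, `family_size`,
#'   `threshold` (= `alpha/family_size`), `significant`.
#' @details When all pooled values are identical the rank variance is zero
#'   and `p` is 1 by convention.
#' @export
mann_whitney_groups <- function(a, b, family_size = 1, alpha = 0.05,
                                exact = FALSE, name = "mann_whitney",
                                groups = c("A", "B")) {
  if (!length(a) || !length(b)) xo_abort("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    u <- length(a) * length(b) / 2
    p <- 1
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    u <- unname(wt$statistic)
    p <- wt$p.value
  }
  thr <- alpha / family_size
  structure(data.frame(test = name,
                       groups = paste(groups, collapse = " vs "),
                       statistic = u, p = p, family_size = family_size,
                       threshold = thr, significant = p < thr,
                       stringsAsFactors = FALSE),
            class = c("xo_comparison", "data.frame"))
}

#' Agresti-Coull binomial confidence interval
#'
#' Adjusted-Wald interval: with `z` the standard-normal quantile at
#' `(1 + conf)/2`, `n~ = n + z^2`, `p~ = (x + z^2/2)/n~`, the interval is
#' `p~ +/- z sqrt(p~ (1 - p~)/n~)`, clipped to `[0, 1]`.
#'
#' @param x successes, `0 <= x <= n` (vectorized).
#' @param n trials, `>= 1`.
#' @param conf confidence level (default 0.95).
#' @return Data frame with columns `estimate` (`x/n`), `lower`, `upper`.
#' @export
agresti_coull_ci <- function(x, n, conf = 0.95) {
  if (any(n < 1)) xo_abort("`n` must be >= 1")
  if (any(x < 0 | x > n)) xo_abort("`x` must be in [0, n]")
  z <- stats::qnorm((1 + conf) / 2)
  nt <- n + z^2
  pt <- (x + z^2 / 2) / nt
  half <- z * sqrt(pt * (1 - pt) / nt)
  data.frame(estimate = x / n,
             lower = pmax(0, pt - half),
             upper = pmin(1, pt + half))
}

#' Per-interval proportions, intervals and Fisher tests for one WT-KO pair
#'
#' For every interval: the event proportion and Agresti-Coull 95% CI in
#' each group, and a two-sided Fisher exact test of the 2x2 table
#' `[[x_A, n_A - x_A], [x_B, n_B - x_B]]`.  The Bonferroni family defaults
#' to (number of tested intervals) x `n_comparisons`; with the full
#' 111-interval reference panel and the two WT-vs-KO comparisons this gives
#' a per-test threshold of 0.05/222 = 0.000225.
#'
#' @param calls a [call_events()] result containing both groups.
#' @param group_a,group_b the two groups to compare (e.g. `"FWT"`, `"FKO"`).
#' @param family_alpha family-wise error rate (default 0.05).
#' @param n_comparisons number of group comparisons sharing the family
#'   (default 2: female and male WT-vs-KO).
#' @param family_size override the derived family size (rarely needed).
#' @param conf confidence level of the per-group intervals.
#' @param max_prop optional sensitivity filter: only intervals whose event
#'   proportion is below this cutoff in both groups are tested (e.g. 0.10
#'   or 0.05); `NULL` tests all intervals.
#' @return Data frame with one row per tested interval: the interval
#'   columns, then `x_a`, `n_a`, `prop_a`, `lower_a`, `upper_a` (same for
#'   `b`), `p_fisher`, `threshold`, `significant`.  Intervals with a zero
#'   denominator on either side are skipped (attribute `skipped`).
#' @export
fisher_intervals <- function(calls, group_a, group_b, family_alpha = 0.05,
                             n_comparisons = 2, family_size = NULL,
                             conf = 0.95, max_prop = NULL) {
  tot <- interval_totals(calls)
  for (g in c(group_a, group_b))
    if (!paste0("x_", g) %in% names(tot))
      xo_abort(sprintf("group %s absent from call set", g))
  xa <- tot[[paste0("x_", group_a)]]; na <- tot[[paste0("n_", group_a)]]
  xb <- tot[[paste0("x_", group_b)]]; nb <- tot[[paste0("n_", group_b)]]

  ok <- na > 0 & nb > 0
  if (!is.null(max_prop)) ok <- ok & (xa / na < max_prop) & (xb / nb < max_prop)
  fam <- family_size %||% (sum(ok) * n_comparisons)
  thr <- family_alpha / fam

  p <- rep(NA_real_, nrow(tot))
  p[ok] <- vapply(which(ok), function(k)
    stats::fisher.test(matrix(c(xa[k], na[k] - xa[k],
                                xb[k], nb[k] - xb[k]),
                              nrow = 2, byrow = TRUE))$p.value, 0)
  ci_a <- agresti_coull_ci(xa[ok], na[ok], conf)
  ci_b <- agresti_coull_ci(xb[ok], nb[ok], conf)
  out <- cbind(
    tot[ok, c("chrom", "left_marker", "right_marker", "span_mbp")],
    data.frame(x_a = xa[ok], n_a = na[ok], prop_a = ci_a$estimate,
               lower_a = ci_a$lower, upper_a = ci_a$upper,
               x_b = xb[ok], n_b = nb[ok], prop_b = ci_b$estimate,
               lower_b = ci_b$lower, upper_b = ci_b$upper,
               p_fisher = p[ok], threshold = thr,
               significant = p[ok] < thr))
  rownames(out) <- NULL
  attr(out, "skipped") <- tot[!ok & !(na > 0 & nb > 0),
                              c("chrom", "left_marker", "right_marker")]
  attr(out, "family_size") <- fam
  out
}

#' Region specifications: centromere- and telomere-proximal SNP pairs
#'
#' The default regions select, per chromosome, the marker interval closest
#' to the centromere (the first SNP pair) or to the telomere (the last SNP
#' pair), for the chromosome subsets used by the reference analysis:
#' centromeric - chromosomes 1, 7, 8, 11, 18, 19 (n = 6 intervals);
#' telomeric - chromosomes 1, 2, 3, 4, 5, 8, 9, 11, 14, 16, 17, 19
#' (n = 12 intervals).
#'
#' @param chroms chromosomes contributing their first/last interval.
#' @param name region label.
#' @return Object of class `region_spec`: data frame with columns `chrom`
#'   and `which` (`"first"`, `"last"`, or a `left_marker..right_marker`
#'   interval name).
#' @export
region_spec <- function(chroms, which, name = "custom") {
  structure(data.frame(chrom = chroms, which = which,
                       stringsAsFactors = FALSE),
            name = name, class = c("region_spec", "data.frame"))
}

#' @rdname region_spec
#' @export
centromeric_region <- function(chroms = c(1, 7, 8, 11, 18, 19))
  region_spec(chroms, "first", "centromeric")

#' @rdname region_spec
#' @export
telomeric_region <- function(chroms = c(1, 2, 3, 4, 5, 8, 9, 11, 14, 16, 17, 19))
  region_spec(chroms, "last", "telomeric")

region_interval_index <- function(region, intervals) {
  vapply(seq_len(nrow(region)), function(i) {
    kk <- which(intervals$chrom == region$chrom[i])
    if (!length(kk))
      xo_abort(sprintf("region references chromosome %d with no interval",
                       region$chrom[i]))
    w <- region$which[i]
    if (w == "first") kk[1]
    else if (w == "last") kk[length(kk)]
    else {
      nm <- paste(intervals$left_marker[kk], intervals$right_marker[kk],
                  sep = "..")
      k <- kk[match(w, nm)]
      if (is.na(k)) xo_abort(sprintf("region interval %s not found", w))
      k
    }
  }, 0L)
}

#' Compare event proportions of a region between two groups
#'
#' Per group, the per-interval event proportions of the region's intervals
#' are collected and averaged (mean +/- SEM over intervals), then the two
#' sets of interval proportions are compared by Mann-Whitney at the
#' Bonferroni-corrected threshold.
#'
#' @param calls a [call_events()] result.
#' @param region a [region_spec()].
#' @param groups the two groups to compare (default `c("FWT", "MWT")`, the
#'   female/male wild-type contrast).
#' @param family_size Bonferroni family (default 4, the four group
#'   contrasts of the global analysis, threshold 0.0125).
#' @param alpha family-wise error rate.
#' @return List with `means` (per group: `mean`, `sem`, `n_intervals`),
#'   `proportions` (matrix intervals x groups) and `comparison` (a
#'   [mann_whitney_groups()] result).
#' @export
region_compare <- function(calls, region, groups = c("FWT", "MWT"),
                           family_size = 4, alpha = 0.05) {
  if (!nrow(region)) xo_abort("empty region")
  tot <- interval_totals(calls)
  idx <- region_interval_index(region, calls$intervals)
  prop <- sapply(groups, function(g) {
    x <- tot[[paste0("x_", g)]][idx]; n <- tot[[paste0("n_", g)]][idx]
    if (any(n == 0)) xo_abort(sprintf("region interval unassessed in group %s", g))
    x / n
  })
  prop <- matrix(prop, ncol = length(groups),
                 dimnames = list(paste(tot$left_marker[idx],
                                       tot$right_marker[idx], sep = ".."),
                                 groups))
  means <- data.frame(
    group = groups,
    n_intervals = nrow(prop),
    mean = colMeans(prop),
    sem = apply(prop, 2, stats::sd) / sqrt(nrow(prop)),
    row.names = NULL, stringsAsFactors = FALSE)
  cmp <- mann_whitney_groups(prop[, 1], prop[, 2], family_size, alpha,
                             name = paste0("region_", attr(region, "name")),
                             groups = groups)
  list(means = means, proportions = prop, comparison = cmp)
}

#' Chromosome-size effect on recombination rate
#'
#' Pools the given groups (by default the two wild-type groups, female and
#' male) and computes, per chromosome, events per sample per Mbp of marker
#' span; returns the ratio of the second chromosome's rate over the
#' first's.  Small chromosomes are expected to recombine at a higher rate
#' per Mbp (at least one crossover per bivalent is needed regardless of
#' size).
#'
#' @param calls a `crossover_calls` or `crossover_counts` object.
#' @param panel the matching retained [marker_panel()].
#' @param chrom_a,chrom_b the chromosomes to compare (defaults 1 and 19,
#'   biggest and smallest mouse autosome).
#' @param groups groups pooled (default `c("FWT", "MWT")`).
#' @return The ratio `rate(chrom_b) / rate(chrom_a)`.
#' @export
size_vs_rate <- function(calls, panel, chrom_a = 1, chrom_b = 19,
                         groups = c("FWT", "MWT")) {
  cs <- chrom_stats(calls, panel)
  for (ch in c(chrom_a, chrom_b))
    if (!ch %in% cs$chrom) xo_abort(sprintf("chromosome %s absent", ch))
  rate <- function(ch) {
    row <- cs[cs$chrom == ch, ]
    x <- sum(vapply(groups, function(g) as.numeric(row[[paste0("x_", g)]]), 0))
    n <- sum(vapply(groups, function(g) as.numeric(row[[paste0("n_", g)]]), 0))
    x / n / row$length_mbp
  }
  ra <- rate(chrom_a)
  if (ra == 0) xo_abort("zero recombination rate on the reference chromosome")
  rate(chrom_b) / ra
}

#' Detection power of a panel against simulator truth
#'
#' Fraction of true crossovers the panel's event calls recover, with a
#' decomposition of the losses: crossovers outside the first-to-last-marker
#' span of their chromosome (`out_of_span`), within-interval cancellation
#' (an even number of crossovers in one interval yields no event,
#' `cancelled`; an odd number k yields one event, losing k - 1), and a
#' residual attributable to missing calls, genotyping error and scenario
#' handling (`residual`).
#'
#' @param calls a [call_events()] result derived from the simulation that
#'   produced `truth`.
#' @param truth the `true_meiosis` object from [simulate_offspring()].
#' @param panel the retained [marker_panel()] the calls were made on.
#' @return List: `fraction` (called/true), `n_true`, `n_called`, and
#'   `losses` (counts: `out_of_span`, `cancelled`, `residual`).
#' @export
detection_power <- function(calls, truth, panel) {
  if (!setequal(unique(truth$sample_id), calls$samples$sample_id))
    xo_abort("`truth` and `calls` cover different samples")
  n_true <- sum(truth$n_xo)
  if (n_true == 0) xo_abort("no true crossover in `truth`; power undefined")
  n_called <- sum(calls$per_sample_total)

  m <- panel$markers
  first <- tapply(m$pos_bp, m$chrom, min)
  last <- tapply(m$pos_bp, m$chrom, max)
  breaks <- split(m$pos_bp, m$chrom)

  out_of_span <- 0L; cancelled <- 0L
  for (r in seq_len(nrow(truth))) {
    ch <- as.character(truth$chrom[r])
    xo <- truth$xo_bp[[r]]
    if (!length(xo)) next
    if (!ch %in% names(breaks)) { out_of_span <- out_of_span + length(xo); next }
    inside <- xo > first[[ch]] & xo <= last[[ch]]
    out_of_span <- out_of_span + sum(!inside)
    if (any(inside)) {
      per_iv <- table(findInterval(xo[inside], breaks[[ch]]))
      cancelled <- cancelled + sum(per_iv - per_iv %% 2)
    }
  }
  residual <- (n_true - n_called) - out_of_span - cancelled
  list(fraction = n_called / n_true, n_true = n_true, n_called = n_called,
       losses = list(out_of_span = out_of_span, cancelled = cancelled,
                     residual = residual))
}
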