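# Independent oracles and small fixtures shared across the suite.
# Oracles deliberately use naive loop/enumeration implementations, kept
# separate from the package's code paths.

# brute-force event rescan for COMPLETE calls (no N): per sample, one event
# per consecutive same-chromosome marker pair whose states differ
oracle_call_matrix <- function(calls, chrom_of) {
  n_iv <- sum(diff(match(chrom_of, unique(chrom_of))) == 0)
  ev <- matrix(NA_integer_, nrow(calls), n_iv)
  for (i in seq_len(nrow(calls))) {
    k <- 0
    for (j in seq_len(ncol(calls) - 1)) {
      if (chrom_of[j] != chrom_of[j + 1]) next
      k <- k + 1
      ev[i, k] <- as.integer(calls[i, j] != calls[i, j + 1])
    }
  }
  ev
}

# two-sided exact binomial p for x successes in n at p = 0.5, by tail sum
oracle_binom_p <- function(x, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# two-sided Fisher exact p by hypergeometric enumeration
oracle_fisher_p <- function(x1, n1, x2, n2) {
  m <- x1 + x2
  k <- max(0, m - n2):min(n1, m)
  d <- dhyper(k, n1, n2, m)
  sum(d[d <= dhyper(x1, n1, n2, m) * (1 + 1e-7)])
}

# Agresti-Coull interval, written out from the published formula
oracle_ac <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  n_tilde <- n + z * z
  p_tilde <- (x + z * z / 2) / n_tilde
  se <- sqrt(p_tilde * (1 - p_tilde) / n_tilde)
  c(max(0, p_tilde - z * se), min(1, p_tilde + z * se))
}

# tiny two-chromosome panel: chrom 1 markers at 10,20,30,40 Mbp,
# chrom 2 at 5,15,25 Mbp
tiny_panel <- function() {
  marker_panel(
    data.frame(chrom = c(1, 1, 1, 1, 2, 2, 2),
               pos_bp = c(10, 20, 30, 40, 5, 15, 25) * 1e6,
               marker_id = c("a1", "a2", "a3", "a4", "b1", "b2", "b3")),
    c("1" = 50, "2" = 30))
}

# genotype matrix from a character-row list, aligned to a panel
gm_from_rows <- function(rows, panel, groups = NULL) {
  calls <- do.call(rbind, rows)
  colnames(calls) <- panel$markers$marker_id
  n <- length(rows)
  genotype_matrix(
    data.frame(sample_id = sprintf("s%02d", seq_len(n)),
               group = groups %||% rep("FWT", n)),
    calls)
}

# dense one-chromosome panel: markers every `step` Mbp across `size` Mbp
dense_panel <- function(size = 100, step = 1, chrom = 1) {
  pos <- seq(step, size - 1, by = step)
  marker_panel(
    data.frame(chrom = chrom, pos_bp = pos * 1e6,
               marker_id = sprintf("d%04d", seq_along(pos))),
    stats::setNames(size, chrom))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
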