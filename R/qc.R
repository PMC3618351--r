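#' Quality-control configuration
#'
#' @param snp_call_threshold markers must have a call rate strictly greater
#'   than this to be retained (default 0.95).
#' @param sample_call_threshold samples must have a call rate strictly
#'   greater than this (default 0.90), computed over retained markers.
#' @param distortion_alpha two-sided significance level of the
#'   transmission-ratio-distortion test: markers whose heterozygote fraction
#'   among non-missing calls rejects `p = 0.5` at this level are dropped
#'   (default 0.01, i.e. exclusion from a 99% acceptance region).
#' @param distortion_exact use the exact binomial test (default) or the
#'   normal approximation.
#' @param scenario how residual missing calls are treated downstream:
#'   `"conservative"` (a missing call never creates an event),
#'   `"liberal"` (missing calls are imputed to maximize the event count) or
#'   `"both"` (pipeline runs both and reports the bracket).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(snp_call_threshold = 0.95,
                      sample_call_threshold = 0.90,
                      distortion_alpha = 0.01,
                      distortion_exact = TRUE,
                      scenario = c("conservative", "liberal", "both")) {
  stopifnot_scalar_prob(snp_call_threshold, "snp_call_threshold",
                        allow_zero = FALSE)
  stopifnot_scalar_prob(sample_call_threshold, "sample_call_threshold",
                        allow_zero = FALSE)
  if (!is.numeric(distortion_alpha) || distortion_alpha <= 0 ||
      distortion_alpha >= 1)
    xo_abort("`distortion_alpha` must be in (0, 1)")
  structure(list(snp_call_threshold = snp_call_threshold,
                 sample_call_threshold = sample_call_threshold,
                 distortion_alpha = distortion_alpha,
                 distortion_exact = distortion_exact,
                 scenario = match.arg(scenario)),
            class = "qc_config")
}

# two-sided p for H-count x out of n non-missing calls against p = 0.5
distortion_p <- function(x, n, exact = TRUE) {
  if (n == 0) return(NA_real_)
  if (exact) stats::binom.test(x, n, 0.5)$p.value
  else {
    z <- (abs(x - n / 2) ) / sqrt(n / 4)
    2 * stats::pnorm(-z)
  }
}

#' Marker-level QC filters
#'
#' Applies, in order: (1) the call-rate filter - markers with a call rate
#' `<= snp_call_threshold` are dropped (`low_call`); (2) among survivors,
#' the transmission-ratio-distortion filter - markers whose heterozygote
#' count among non-missing calls rejects the 50% inheritance null at
#' `distortion_alpha` (two-sided, exact binomial by default) are dropped
#' (`distortion`).  Filters are computed on the full cohort pooled across
#' groups.  Chromosomes left with fewer than two retained markers are
#' removed from the panel (no interval remains).
#'
#' @param gm a [genotype_matrix()].
#' @param panel the matching [marker_panel()].
#' @param config a [qc_config()].
#' @return List with `genotypes` (retained columns), `panel` (reduced) and
#'   `report`, a data frame with one row per dropped marker: `marker_id`,
#'   `reason` (`low_call`/`distortion`/`single_on_chrom`), `call_rate`,
#'   `n_called`, `n_het`, `p_distortion`.
#' @export
filter_markers <- function(gm, panel, config = qc_config()) {
  if (nrow(gm$calls) == 0L) xo_abort("empty genotype matrix")
  if (!identical(colnames(gm$calls), panel$markers$marker_id))
    xo_abort("genotypes are not aligned to `panel`")
  called <- gm$calls != "N"
  call_rate <- colMeans(called)
  n_called <- colSums(called)
  n_het <- colSums(gm$calls == "H")
  p_dist <- vapply(seq_along(n_called), function(j)
    distortion_p(n_het[j], n_called[j], config$distortion_exact), 0)

  low <- call_rate <= config$snp_call_threshold
  dist <- !low & !is.na(p_dist) & p_dist < config$distortion_alpha
  drop <- low | dist

  report <- data.frame(marker_id = colnames(gm$calls),
                       reason = ifelse(low, "low_call",
                                       ifelse(dist, "distortion", "")),
                       call_rate = call_rate, n_called = n_called,
                       n_het = n_het, p_distortion = p_dist,
                       stringsAsFactors = FALSE, row.names = NULL)

  keep_ids <- colnames(gm$calls)[!drop]
  sub <- subset_panel(panel, keep_ids)
  lost <- setdiff(keep_ids, sub$panel$markers$marker_id)
  report$reason[report$marker_id %in% lost] <- "single_on_chrom"
  report <- report[report$reason != "", , drop = FALSE]

  keep_ids <- sub$panel$markers$marker_id
  gm2 <- genotype_matrix(gm$samples, gm$calls[, keep_ids, drop = FALSE])
  list(genotypes = gm2, panel = sub$panel, report = report)
}

#' Sample-level QC filter
#'
#' Drops samples whose call rate over the retained markers is
#' `<= sample_call_threshold`.  Apply after [filter_markers()] so call
#' rates reflect the retained panel.
#'
#' @inheritParams filter_markers
#' @return List with `genotypes` and `report` (dropped samples:
#'   `sample_id`, `group`, `call_rate`).
#' @export
filter_samples <- function(gm, config = qc_config()) {
  if (nrow(gm$calls) == 0L) xo_abort("empty genotype matrix")
  call_rate <- rowMeans(gm$calls != "N")
  drop <- call_rate <= config$sample_call_threshold
  report <- data.frame(sample_id = gm$samples$sample_id,
                       group = gm$samples$group,
                       call_rate = call_rate,
                       stringsAsFactors = FALSE, row.names = NULL)[drop, ]
  gm2 <- genotype_matrix(gm$samples[!drop, , drop = FALSE],
                         gm$calls[!drop, , drop = FALSE])
  list(genotypes = gm2, report = report)
}

# liberal imputation of one sample's calls on one chromosome: alternate the
# genotype state through every missing run so that every interval touching a
# missing call becomes a transition where the run's parity allows it (this
# attains the per-run maximum event count; see vignette).
impute_liberal_row <- function(calls) {
  miss <- calls == "N"
  if (!any(miss)) return(calls)
  obs <- which(!miss)
  if (!length(obs)) return(calls)        # fully missing: nothing to anchor on
  flip <- function(x) ifelse(x == "B", "H", "B")
  # leading run: alternate right-to-left from the first observed call
  first <- obs[1]
  if (first > 1)
    for (i in seq(first - 1, 1)) calls[i] <- flip(calls[i + 1])
  # interior and trailing runs: alternate left-to-right
  for (i in seq_along(calls)[-seq_len(first)])
    if (calls[i] == "N") calls[i] <- flip(calls[i - 1])
  calls
}

#' Resolve missing calls under an extreme scenario
#'
#' Residual missing calls among retained markers/samples are handled by one
#' of two extreme scenarios bracketing the truth: under `"conservative"`
#' a missing call never creates an event (event calling compares the
#' flanking non-missing calls, so the matrix is returned unchanged and only
#' annotated); under `"liberal"` every missing call is imputed, per
#' chromosome, to the state that maximizes the number of called events.
#'
#' @param gm a [genotype_matrix()].
#' @param panel the matching [marker_panel()].
#' @param scenario `"conservative"` or `"liberal"`.
#' @return The genotype matrix, with attribute `scenario` set; under
#'   `"liberal"` all imputable `N` cells are replaced.
#' @export
apply_missing_scenario <- function(gm, panel,
                                   scenario = c("conservative", "liberal")) {
  scenario <- match.arg(scenario)
  if (scenario == "liberal" && nrow(gm$calls) > 0) {
    chrom_of <- panel$markers$chrom
    for (ch in unique(chrom_of)) {
      jj <- which(chrom_of == ch)
      has_n <- which(rowSums(gm$calls[, jj, drop = FALSE] == "N") > 0)
      for (i in has_n)
        gm$calls[i, jj] <- impute_liberal_row(gm$calls[i, jj])
    }
  }
  attr(gm, "scenario") <- scenario
  gm
}

#' Run the full QC stage
#'
#' [filter_markers()], then [filter_samples()], then
#' [apply_missing_scenario()] (for `scenario = "both"` the returned
#' genotypes keep their `N` cells and both scenarios are applied at event
#' calling).
#'
#' @inheritParams filter_markers
#' @return List of class `qc_result`: `genotypes`, `panel`, `report`
#'   (fields `dropped_markers`, `dropped_samples`, `n_missing_retained`,
#'   `dims_in`, `dims_out`, `scenario`).
#' @export
run_qc <- function(gm, panel, config = qc_config()) {
  fm <- filter_markers(gm, panel, config)
  fs <- filter_samples(fm$genotypes, config)
  n_missing <- sum(fs$genotypes$calls == "N")
  out <- fs$genotypes
  if (config$scenario != "both")
    out <- apply_missing_scenario(out, fm$panel, config$scenario)
  structure(list(
    genotypes = out, panel = fm$panel,
    report = list(dropped_markers = fm$report,
                  dropped_samples = fs$report,
                  n_missing_retained = n_missing,
                  dims_in = dim(gm$calls), dims_out = dim(out$calls),
                  scenario = config$scenario)),
    class = "qc_result")
}
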