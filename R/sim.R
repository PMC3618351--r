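# Synthetic meiosis: crossovers on the four-chromatid bundle follow a
# stationary gamma renewal process (Housworth-Stahl without the
# interference-escape pathway).  Inter-event distances are
# Gamma(shape = nu, rate = 2 * nu) in Morgans, so bundle events occur at
# rate 2 per Morgan; each event is retained on the transmitted chromatid
# with probability 1/2, giving the map's expected 1 crossover per Morgan.
# nu = 1 recovers a Poisson process (no interference); nu > 1 spaces
# events out (positive interference, underdispersed counts).

#' Simulate the crossovers of one transmitted gamete
#'
#' Draws crossover positions for a single chromosome of a single gamete
#' from a stationary gamma renewal model with chromatid thinning, then maps
#' genetic positions to physical positions by linear cM-bp scaling.
#'
#' @param chrom_size_bp physical chromosome size in bp.
#' @param map_cM genetic length of the whole chromosome in cM (expected
#'   number of crossovers on the transmitted chromatid = `map_cM / 100`).
#' @param nu gamma shape `>= 1`; 1 = no interference.
#' @param obligate_chiasma if `TRUE`, bundles with zero events are rejected
#'   and redrawn (at least one chiasma per bivalent); the retained gamete
#'   may still carry zero crossovers.
#' @return Numeric vector of crossover positions in bp, strictly increasing,
#'   in `(0, chrom_size_bp]`; `numeric(0)` when no crossover is transmitted.
#' @details The first inter-event distance is drawn from the stationary
#'   (equilibrium) renewal distribution: the spacing covering the origin is
#'   length-biased, `Gamma(nu + 1, 2 nu)`, and the origin is uniform within
#'   it.  Uses R's global RNG; seed via [set.seed()] or [sim_config()].
#' @export
simulate_gamete <- function(chrom_size_bp, map_cM, nu = 10,
                            obligate_chiasma = FALSE) {
  if (map_cM < 0) xo_abort("`map_cM` must be >= 0")
  if (nu < 1) xo_abort("`nu` must be >= 1")
  L <- map_cM / 100                      # chromosome length in Morgans
  if (L == 0) return(numeric(0))
  rate <- 2 * nu
  repeat {
    # stationary first event, then ordinary renewals
    ev <- stats::runif(1) * stats::rgamma(1, shape = nu + 1, rate = rate)
    events <- numeric(0)
    while (ev < L) {
      events <- c(events, ev)
      ev <- ev + stats::rgamma(1, shape = nu, rate = rate)
    }
    if (!obligate_chiasma || length(events) > 0) break
  }
  if (!length(events)) return(numeric(0))
  kept <- events[stats::runif(length(events)) < 0.5]
  unname(kept / L * chrom_size_bp)
}

#' Simulator configuration
#'
#' @param panel a [marker_panel()] to genotype against.
#' @param group_sizes named integer vector of offspring per group, names in
#'   [group_codes()]; groups whose F1 parent is female (`FWT`, `FKO`) use
#'   `map_female`, the others `map_male`.
#' @param map_female,map_male named numeric vectors, chromosome -> genetic
#'   length in cM (see [ref_genetic_map()]); must cover every chromosome of
#'   the panel.
#' @param nu gamma interference shape, `>= 1` (default 10, a conventional
#'   mouse-scale interference strength).
#' @param missing_rate per-call probability of an `N` (default 0.005).
#' @param error_rate per-call probability of a B/H flip (default 0).
#' @param obligate_chiasma require >= 1 bundle event per chromosome
#'   (default `FALSE`).
#' @param seed integer RNG seed; identical configuration and seed give
#'   bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(panel,
                       group_sizes = ref_group_sizes(),
                       map_female = ref_genetic_map("female"),
                       map_male = ref_genetic_map("male"),
                       nu = 10, missing_rate = 0.005, error_rate = 0,
                       obligate_chiasma = FALSE, seed = 1L) {
  if (!inherits(panel, "marker_panel")) xo_abort("`panel` must be a marker_panel")
  bad <- setdiff(names(group_sizes), group_codes())
  if (length(bad) || is.null(names(group_sizes)))
    xo_abort("`group_sizes` must be named with group codes")
  if (any(group_sizes < 0)) xo_abort("group sizes must be >= 0")
  chroms <- as.character(unique(panel$markers$chrom))
  for (m in list(map_female, map_male)) {
    if (!all(chroms %in% names(m)))
      xo_abort("genetic map does not cover every panel chromosome")
    if (any(m < 0)) xo_abort("map lengths must be >= 0")
  }
  if (nu < 1) xo_abort("`nu` must be >= 1")
  stopifnot_scalar_prob(missing_rate, "missing_rate")
  stopifnot_scalar_prob(error_rate, "error_rate")
  structure(list(panel = panel, group_sizes = group_sizes,
                 map_female = map_female, map_male = map_male, nu = nu,
                 missing_rate = missing_rate, error_rate = error_rate,
                 obligate_chiasma = obligate_chiasma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a backcross cohort
#'
#' For every offspring, one F1 gamete is simulated per chromosome
#' ([simulate_gamete()]) with the map of the sex of its F1 parent; each
#' marker reads `H` where the gamete carries the BALB/c allele and `B`
#' where it carries C57BL/6J.  Genotyping noise (B/H flips) and missing
#' calls are then applied.  Ground truth is recorded before corruption.
#'
#' @param config a [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (class `true_meiosis`): data frame with one row per sample x
#'   chromosome: `sample_id`, `group`, `chrom`, `start_balb` (does the
#'   gamete start, at position 0, on the BALB/c haplotype), `n_xo`, and a
#'   list column `xo_bp` of crossover positions.
#' @export
simulate_offspring <- function(config) {
  if (!inherits(config, "sim_config")) xo_abort("`config` must be a sim_config")
  set.seed(config$seed)
  panel <- config$panel
  chroms <- unique(panel$markers$chrom)
  sizes_bp <- panel$chrom_sizes[as.character(chroms)] * 1e6
  marker_pos <- split(panel$markers$pos_bp, panel$markers$chrom)[as.character(chroms)]

  groups <- rep(names(config$group_sizes), config$group_sizes)
  n <- length(groups)
  ids <- sprintf("%s_%03d", groups, stats::ave(seq_len(n), groups, FUN = seq_along))

  calls <- matrix("B", nrow = n, ncol = nrow(panel$markers),
                  dimnames = list(ids, panel$markers$marker_id))
  truth <- vector("list", n * length(chroms))
  k <- 0L
  for (i in seq_len(n)) {
    map <- if (group_sex(groups[i]) == "female") config$map_female
           else config$map_male
    row <- character(0)
    for (j in seq_along(chroms)) {
      ch <- chroms[j]
      xo <- simulate_gamete(sizes_bp[j], map[[as.character(ch)]], config$nu,
                            config$obligate_chiasma)
      start_balb <- stats::runif(1) < 0.5
      # allele at a marker flips at every crossover to its left
      n_left <- findInterval(marker_pos[[j]], xo)
      balb <- xor(start_balb, n_left %% 2 == 1)
      row <- c(row, ifelse(balb, "H", "B"))
      k <- k + 1L
      truth[[k]] <- list(sample_id = ids[i], group = groups[i], chrom = ch,
                         start_balb = start_balb, n_xo = length(xo),
                         xo_bp = xo)
    }
    calls[i, ] <- row
  }
  # genotyping noise, then dropout (ground truth already recorded)
  if (config$error_rate > 0 && length(calls)) {
    flip <- stats::runif(length(calls)) < config$error_rate
    calls[flip] <- ifelse(calls[flip] == "B", "H", "B")
  }
  if (config$missing_rate > 0 && length(calls)) {
    calls[stats::runif(length(calls)) < config$missing_rate] <- "N"
  }
  truth_df <- data.frame(
    sample_id = vapply(truth, `[[`, "", "sample_id"),
    group = vapply(truth, `[[`, "", "group"),
    chrom = vapply(truth, `[[`, 0L, "chrom"),
    start_balb = vapply(truth, `[[`, NA, "start_balb"),
    n_xo = vapply(truth, `[[`, 0L, "n_xo"),
    stringsAsFactors = FALSE)
  truth_df$xo_bp <- lapply(truth, `[[`, "xo_bp")
  class(truth_df) <- c("true_meiosis", "data.frame")

  list(genotypes = genotype_matrix(
         data.frame(sample_id = ids, group = groups, stringsAsFactors = FALSE),
         calls),
       truth = truth_df)
}

#' Write / read simulator ground truth
#'
#' Serialized as TSV: `sample_id`, `group`, `chrom`, `start_balb`, and
#' `xo_bp` as a comma-separated position list.
#'
#' @param truth a `true_meiosis` data frame from [simulate_offspring()].
#' @param path destination/source file.
#' @return `path` invisibly / the `true_meiosis` object.
#' @export
write_truth <- function(truth, path) {
  out <- truth[c("sample_id", "group", "chrom", "start_balb")]
  out$xo_bp <- vapply(truth$xo_bp, function(x)
    paste(format(x, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = ","), "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(xo_bp = "character"))
  tab$xo_bp <- lapply(strsplit(tab$xo_bp, ","), function(x)
    as.numeric(x[nzchar(x)]))
  tab$n_xo <- lengths(tab$xo_bp)
  tab <- tab[c("sample_id", "group", "chrom", "start_balb", "n_xo", "xo_bp")]
  class(tab) <- c("true_meiosis", "data.frame")
  tab
}
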