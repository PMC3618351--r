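# Bundled reference dataset: the geometry of a published 130-SNP Sequenom
# panel spanning the 19 mouse autosomes (NCBI build36 sizes), and the
# per-chromosome crossover counts observed in the four backcross groups
# genotyped with it (FWT/FKO n = 79, MWT/MKO n = 78).
#
# Only per-chromosome aggregates of the panel were published (marker count,
# min/mean/max inter-marker distance, first-to-last length), not individual
# SNP positions, so ref_panel() lays out SYNTHETIC positions that reproduce
# those aggregates: per chromosome the first gap equals the published
# minimum, the last gap the published maximum, and the interior gaps are
# equal.  Where the published mean distance and first-to-last length are
# mutually inconsistent at the printed precision (their rounding bands do
# not overlap: an artefact of independent rounding), the length used lies in
# the intersection of both rounding bands, so every printed cell is still
# reproduced at its printed precision.

.ref_geometry <- function() {
  data.frame(
    chrom = 1:19,
    size_mbp = c(197, 182, 160, 156, 153, 150, 153, 132, 124, 130,
                 122, 121, 120, 125, 103, 98, 95, 91, 61),
    n_snps = c(13L, 7L, 8L, 9L, 9L, 6L, 9L, 9L, 6L, 5L,
               7L, 4L, 7L, 8L, 5L, 5L, 5L, 4L, 4L),
    min_gap = c(8.69, 9.93, 11.37, 11.81, 8.17, 12.45, 12.31, 9.69, 10.73,
                13.03, 6.93, 12.64, 13.58, 8.98, 12.74, 10.62, 7.05, 11.89,
                7.97),
    max_gap = c(30.36, 74.98, 46.28, 31.86, 44.27, 61.62, 33.07, 20.33,
                30.78, 48.46, 30.59, 31.87, 28.97, 20.84, 16.28, 30.33,
                30.49, 16.51, 29.87),
    # first-to-last span; six entries deviate from the printed 1-dp value by
    # < 0.05 Mbp to stay consistent with the printed mean gap (see above)
    length_mbp = c(187.5, 173.6, 145.4725, 144.665, 143.1, 136.5375, 132.7,
                   117.7, 82.8, 104.2, 111.7, 70.92, 103.9, 97.4, 60.5,
                   70.17, 84.2, 42.5, 51.4425))
}

#' Reference chromosome sizes
#'
#' Physical sizes (Mbp, NCBI build36) of the 19 mouse autosomes used by the
#' bundled reference panel.
#'
#' @return Named numeric vector, autosome id -> size in Mbp.
#' @export
ref_chrom_sizes <- function() {
  g <- .ref_geometry()
  stats::setNames(g$size_mbp, g$chrom)
}

#' Bundled reference marker panel (synthetic positions)
#'
#' A 130-SNP panel across the 19 mouse autosomes with 111 intervals, mean
#' inter-marker distance 18.57 Mbp and mean per-chromosome maximal distance
#' ("resolution power") 34.62 Mbp.  Marker positions are synthetic: the
#' published description of the panel gives only per-chromosome aggregates,
#' which this layout reproduces exactly (see the package source for the
#' construction).  The first marker of every chromosome sits at 3 Mbp.
#'
#' @param first_marker_mbp offset of the first marker on each chromosome,
#'   in Mbp (default 3; positions of real SNP panels avoid the centromeric
#'   repeat region).
#' @return A [marker_panel()] with 130 markers.
#' @export
ref_panel <- function(first_marker_mbp = 3) {
  g <- .ref_geometry()
  rows <- lapply(seq_len(nrow(g)), function(i) {
    n <- g$n_snps[i]
    mid <- (g$length_mbp[i] - g$min_gap[i] - g$max_gap[i]) / (n - 3L)
    gaps <- c(g$min_gap[i], rep(mid, n - 3L), g$max_gap[i])
    pos <- (first_marker_mbp + cumsum(c(0, gaps))) * 1e6
    data.frame(chrom = g$chrom[i], pos_bp = round(pos),
               marker_id = sprintf("c%02d_s%02d", g$chrom[i], seq_len(n)),
               stringsAsFactors = FALSE)
  })
  marker_panel(do.call(rbind, rows), ref_chrom_sizes())
}

#' Reference per-chromosome crossover counts
#'
#' Crossover events detected per chromosome in each of the four backcross
#' groups of the reference dataset (group sizes FWT = 79, FKO = 79,
#' MWT = 78, MKO = 78; grand total 3629 events).
#'
#' @return Data frame with columns `chrom`, `FWT`, `FKO`, `MWT`, `MKO`.
#' @seealso [callset_from_counts()] to turn these counts into an object the
#'   summary statistics accept, [ref_group_sizes()].
#' @export
ref_event_counts <- function() {
  data.frame(
    chrom = 1:19,
    FWT = c(79, 83, 63, 74, 63, 59, 66, 50, 38, 50, 59, 28, 61, 35, 25, 24,
            47, 17, 50),
    FKO = c(68, 79, 63, 65, 66, 54, 62, 56, 39, 46, 59, 40, 45, 41, 19, 42,
            56, 22, 49),
    MWT = c(70, 76, 48, 50, 59, 51, 47, 42, 34, 36, 57, 25, 32, 37, 25, 34,
            39, 10, 57),
    MKO = c(65, 68, 54, 49, 66, 55, 55, 48, 36, 41, 61, 27, 34, 41, 16, 31,
            57, 4, 50))
}

#' Reference group sizes
#'
#' @return Named integer vector of offspring counts per analysis group in
#'   the reference dataset.
#' @export
ref_group_sizes <- function() {
  c(FWT = 79L, FKO = 79L, MWT = 78L, MKO = 78L)
}

#' Reference per-chromosome map densities
#'
#' Observed map density (cM/Mbp: recombination frequency divided by the
#' physical length of the marker span) per chromosome and group in the
#' reference dataset, as published (two decimals).
#'
#' @return Data frame with columns `chrom`, `FWT`, `FKO`, `MWT`, `MKO`.
#' @export
ref_map_density <- function() {
  data.frame(
    chrom = 1:19,
    FWT = c(0.53, 0.61, 0.55, 0.65, 0.56, 0.55, 0.63, 0.54, 0.58, 0.61,
            0.67, 0.50, 0.74, 0.45, 0.52, 0.43, 0.71, 0.51, 1.23),
    FKO = c(0.46, 0.58, 0.55, 0.57, 0.58, 0.50, 0.59, 0.60, 0.60, 0.56,
            0.67, 0.71, 0.55, 0.53, 0.40, 0.76, 0.84, 0.66, 1.21),
    MWT = c(0.48, 0.56, 0.42, 0.44, 0.53, 0.48, 0.45, 0.46, 0.53, 0.44,
            0.65, 0.45, 0.39, 0.49, 0.53, 0.62, 0.59, 0.30, 1.42),
    MKO = c(0.44, 0.50, 0.48, 0.43, 0.59, 0.52, 0.53, 0.52, 0.56, 0.50,
            0.70, 0.49, 0.42, 0.54, 0.34, 0.57, 0.87, 0.12, 1.25))
}

#' Sex-specific genetic map derived from the reference rates
#'
#' Builds a per-chromosome genetic length (cM) for the simulator from the
#' observed wild-type map densities of the reference dataset:
#' `cM = (cM/Mbp observed in the WT group of that sex) x (full chromosome
#' size in Mbp) x scale`.  The observed densities are computed over the
#' marker span only; multiplying by the full chromosome size extrapolates
#' the same density to the whole chromosome, so crossovers can also fall
#' outside the region the panel covers - which is exactly the dominant
#' source of undetected events for a sparse panel.
#'
#' @param sex `"female"` or `"male"` (sex of the F1 parent).
#' @param scale positive multiplier applied to every chromosome, default
#'   `1/0.83`: the reference study estimated that its panel detects about
#'   83% of all crossovers, so scaling the detected map up by 1/0.83 makes
#'   the simulated truth comparable to dense-map estimates.
#' @return Named numeric vector, autosome id -> genetic length in cM.
#' @export
ref_genetic_map <- function(sex = c("female", "male"), scale = 1 / 0.83) {
  sex <- match.arg(sex)
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    xo_abort("`scale` must be a single positive number")
  dens <- ref_map_density()
  g <- .ref_geometry()
  wt <- if (sex == "female") dens$FWT else dens$MWT
  stats::setNames(wt * g$size_mbp * scale, g$chrom)
}
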