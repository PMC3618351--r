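---
title: "Mapping meiotic crossovers from sparse backcross SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping meiotic crossovers from sparse backcross SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xomap)
```

## The measurement

In a (C57BL/6J × BALB/c)F1 × C57BL/6J backcross, every offspring inherits
one intact C57BL/6J genome from the backcross parent and one F1 gamete.
At any SNP that distinguishes the two strains the offspring is therefore
either homozygous C57BL/6J (`B`: the F1 transmitted its B6 allele) or
heterozygous (`H`: it transmitted BALB/c). A row of genotypes read along a
chromosome is a direct read-out of the transmitted gamete's haplotype, and
a **crossover** is visible as a `B`↔`H` state change between two
consecutive informative SNPs.

Three facts shape everything downstream:

1. An interval between consecutive SNPs reveals **at most one** event per
   meiosis — an even number of crossovers inside it cancels to nothing,
   an odd number collapses to one. Sparse panels therefore undercount.
2. Events strictly outside the first-to-last-marker span of a chromosome
   are invisible. For the bundled 130-SNP panel the spanned fraction is
   2061 of 2473 Mbp ≈ 83%, and this — not cancellation — dominates the
   deficit relative to dense-map studies, because crossover interference
   makes two crossovers in one ~19 Mbp interval rare.
3. Each sample–interval observation is Bernoulli, so the natural
   per-interval summary is a proportion with a binomial interval, and the
   natural per-sample summary is a count (100 × mean count = cM).

## The synthetic-meiosis model

`simulate_gamete()` draws crossover locations on the four-chromatid bundle
from a **stationary gamma renewal process**: inter-event distances are
Gamma(shape ν, rate 2ν) in Morgans, so bundle events occur at 2 per Morgan
with coefficient of variation 1/√ν. Each event is retained on the
transmitted chromatid with probability 1/2 (no chromatid interference),
giving the required 1 crossover per Morgan in expectation for any ν. This
is the Housworth–Stahl counting-model family without the
interference-escape pathway: ν = 1 is a Poisson process (no interference);
larger ν spaces events more evenly (counts become underdispersed). The
stationary start uses the exact construction: the spacing covering the
origin is length-biased, Gamma(ν + 1, 2ν), and the origin is uniform
inside it.

Defaults, and why:

* **ν = 10.** The package must only *exhibit* positive interference, not
  estimate it; ν ≈ 10 is a conventional mouse-scale strength and is a
  plain argument. Detection-power results tolerate a band precisely
  because ν is not pinned by the reference data.
* **Genetic maps** come from `ref_genetic_map(sex, scale)`: the observed
  wild-type map density of each chromosome (cM/Mbp over the marker span)
  extrapolated to the full NCBI chromosome size, times `scale`. The
  default `scale = 1/0.83` compensates the sparse panel's ≈17% detection
  deficit so the simulated truth is comparable to dense-map estimates.
  The cM↔bp map is linear per chromosome; hotspot structure is out of
  scope, so positions within an interval are uniform.
* **Sex difference** enters through map length only (female maps are
  ≈16% longer); centromere/telomere shape differences are not simulated —
  a deliberate simplification, which is why region-level contrasts on
  simulated data are expected to be null.
* **missing_rate = 0.005** per call (independent Bernoulli), which keeps
  simulated call rates comfortably above the 95%/90% QC thresholds;
  clustered assay failure is not modelled. **error_rate = 0** by default:
  genotyping error is available for sensitivity runs, not part of the
  stated world.
* **No obligate chiasma** by default; `obligate_chiasma = TRUE` rejects
  zero-event bundles if wanted.

Ground truth (crossover positions per gamete) is recorded before noise is
applied, which is what makes detection power measurable:
`detection_power()` decomposes the loss into out-of-span events,
within-interval cancellation, and a residual due to missing/error
handling.

What a green simulation test does — and does not — establish: it shows
the *pipeline arithmetic* is right under a model with linear maps,
independent dropout and renewal interference. It says nothing about
hotspot clustering, segregation distortion from real viability effects,
or clustered assay failure, none of which the generator emulates.

## Quality control

* **Marker call-rate filter:** retain markers with call rate strictly
  greater than 0.95 ("more than 95%" — the comparison is deliberately
  strict, so 19/20 fails).
* **Transmission-ratio distortion:** among survivors, a marker whose
  heterozygote count among non-missing calls rejects a two-sided exact
  binomial test of p = 0.5 at α = 0.01 is dropped. "Exclusion from the
  99% confidence region" is operationalised as the exact test; a
  normal-approximation variant is exposed (`distortion_exact = FALSE`)
  because the original analysis tool is unknown. At n ≈ 314 the exact
  test's achievable size is slightly below 0.01 (discreteness), which the
  suite checks analytically rather than assuming.
* **Sample call-rate filter:** strictly greater than 0.90, computed over
  retained markers (order matters and is fixed: markers first).
* Chromosomes left with one retained marker are removed — they define no
  interval.

Residual missing calls among retained sample×marker pairs are handled by
two bracketing scenarios. **Conservative:** a missing call never creates
an event; the scan compares the nearest non-missing flanks, and if they
differ the single event is assigned to the first interval of the gap while
the remaining gap intervals are marked not-assessed (excluded from that
interval's denominator — the reference analysis states no convention, so
the conservative reading is used and logged here). **Liberal:** every
missing call is imputed by alternating the state through the run. A parity
argument shows this attains the per-run maximum: across a run of k missing
cells the number of transitions has fixed parity (even if the flanks
agree, odd otherwise) and is bounded by k + 1; alternating achieves k or
k + 1 accordingly. Conservative totals can therefore never exceed liberal
totals, which is asserted property-style.

## Statistics

* **Group means:** mean events per meiosis ± SEM per group; the
  sex-averaged value is the unweighted mean of the female and male group
  means.
* **Mann–Whitney** (normal approximation with tie and continuity
  corrections; exact option for small n) with Bonferroni thresholds always
  *derived* (α / family size): the four global contrasts give 0.0125. A
  zero-variance pooled sample yields p = 1 by convention.
* **Per-interval proportions** carry Agresti–Coull 95% intervals
  (ñ = n + z², p̃ = (x + z²/2)/ñ, p̃ ± z√(p̃(1−p̃)/ñ), clipped) and
  WT-vs-KO **Fisher exact** tests (two-sided by the probability-ordering
  rule, not doubling). The family is the post-QC interval count times the
  number of comparisons — 111 × 2 ⇒ 0.05/222 ≈ 0.000225 on the full
  panel — never hard-coded. A sensitivity flag restricts testing to
  intervals with proportions below 10% or 5%, where double-crossover
  censoring is least plausible.
* **Region contrasts** average per-interval proportions over the first
  (centromere-proximal) or last (telomere-proximal) interval of fixed
  chromosome sets (n = 6 and n = 12 intervals); averaging is over
  intervals, not mice — the published caption's n values force that
  reading.
* **Chromosome-size effect:** pooled WT events per sample per Mbp,
  chr19 vs chr1; the reference counts give ≈ 2.62.

## Numerical choices and degenerate inputs

* Positions are stored in bp (1-based) and only converted to Mbp for
  reporting; tables round to 2 decimals at the display/test boundary,
  never internally.
* The bundled panel's positions are synthetic: only per-chromosome
  aggregates of the real panel were published. Six chromosomes'
  published mean-distance and length cells are mutually inconsistent at
  printed precision; the fixture's lengths sit in the intersection of the
  two rounding bands so every printed cell is still reproduced.
* Empty cohorts, all-missing chromosomes, zero-denominator intervals and
  zero-rate chromosomes fail loudly (classed errors) or are excluded with
  a log entry, as documented per function.
* All randomness flows from one integer seed; identical configuration and
  seed give byte-identical outputs, including `summary.json`.

## Known limitations

Hotspot-scale maps, gene conversion, chromatid interference, X-chromosome
analysis and positional refinement of crossovers within an interval are
out of scope. The reference study's Mann–Whitney p-values for its cohort
cannot be reproduced (per-sample distributions were not published); the
suite checks the qualitative pattern — a significant female/male contrast
and null genotype contrasts — on simulated data instead.
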