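Package: xomap
Title: Crossover Mapping from Backcross SNP Genotypes
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects meiotic crossover events in (C57BL/6J x BALB/c)F1 x
    C57BL/6J backcross offspring from sparse SNP genotype panels.
    Provides marker-panel and genotype containers with TSV readers and
    writers, marker- and sample-level quality control (call-rate and
    transmission-ratio-distortion filters, conservative/liberal handling
    of missing calls), crossover event calling between consecutive
    informative SNPs, genetic-map summaries (cM and cM/Mbp per
    chromosome), and the group-comparison statistics used in
    recombination-frequency studies (Mann-Whitney with Bonferroni,
    Agresti-Coull binomial intervals, Fisher exact tests per SNP pair,
    centromeric/telomeric region contrasts).  A synthetic-meiosis
    simulator with gamma-renewal crossover interference generates
    backcross genotype matrices with ground-truth crossover positions so
    detection power of a marker panel can be estimated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
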