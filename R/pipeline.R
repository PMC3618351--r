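#' Pipeline configuration
#'
#' Exactly one of `genotypes_path` (real data) or `sim` (synthetic run)
#' must be given.
#'
#' @param out_dir output directory (created if absent).
#' @param panel_path,chrom_sizes_path marker panel TSVs ([read_panel()]);
#'   ignored when `panel` is given directly.
#' @param panel a [marker_panel()]; default [ref_panel()] for synthetic runs.
#' @param genotypes_path TSV of observed genotypes ([read_genotypes()]).
#' @param sim a [sim_config()] for a synthetic run.
#' @param qc a [qc_config()].
#' @param regions list of [region_spec()]s to compare (default the
#'   centromeric and telomeric specs).
#' @param interval_cutoff optional `max_prop` passed to
#'   [fisher_intervals()] (e.g. 0.10 or 0.05), `NULL` for none.
#' @param seed integer; seeds every random stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            panel = NULL, panel_path = NULL,
                            chrom_sizes_path = NULL,
                            genotypes_path = NULL, sim = NULL,
                            qc = qc_config(),
                            regions = list(centromeric_region(),
                                           telomeric_region()),
                            interval_cutoff = NULL,
                            seed = 1L) {
  if (is.null(genotypes_path) == is.null(sim))
    xo_abort("exactly one of `genotypes_path` or `sim` must be set")
  if (is.null(panel) && is.null(panel_path) && is.null(sim))
    xo_abort("a panel is required for real-data runs")
  structure(list(out_dir = out_dir, panel = panel, panel_path = panel_path,
                 chrom_sizes_path = chrom_sizes_path,
                 genotypes_path = genotypes_path, sim = sim, qc = qc,
                 regions = regions, interval_cutoff = interval_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; `sim` and
#' `qc` are nested maps of the corresponding constructor arguments, and a
#' `sim` map may use `panel: ref` plus `map_scale` to request the bundled
#' reference panel and maps.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      xo_abort("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)

  panel <- NULL
  if (!is.null(raw$panel_path))
    panel <- read_panel(raw$panel_path, raw$chrom_sizes_path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    s <- raw$sim
    sim_panel <- if (is.null(s$panel) || identical(s$panel, "ref")) ref_panel()
                 else panel
    scale <- s$map_scale %||% (1 / 0.83)
    gs <- unlist(s$group_sizes %||% ref_group_sizes())
    sim <- sim_config(sim_panel, gs,
                      map_female = ref_genetic_map("female", scale),
                      map_male = ref_genetic_map("male", scale),
                      nu = s$nu %||% 10,
                      missing_rate = s$missing_rate %||% 0.005,
                      error_rate = s$error_rate %||% 0,
                      obligate_chiasma = isTRUE(s$obligate_chiasma),
                      seed = raw$seed %||% 1L)
    panel <- sim_panel
  }
  qc_args <- raw$qc %||% list()
  qc <- do.call(qc_config, qc_args)
  pipeline_config(out_dir = raw$out_dir %||% ".",
                  panel = panel,
                  genotypes_path = raw$genotypes_path,
                  sim = sim, qc = qc,
                  interval_cutoff = raw$interval_cutoff,
                  seed = raw$seed %||% 1L)
}

write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

run_scenario <- function(gm, panel, scenario, cfg) {
  gm <- apply_missing_scenario(gm, panel, scenario)
  calls <- call_events(gm, panel)
  grps <- unique(calls$samples$group)
  cs <- chrom_stats(calls, panel)
  gmeans <- group_means(calls)

  comparisons <- list()
  pairs <- list(c("FWT", "MWT"), c("FKO", "MKO"), c("FWT", "FKO"),
                c("MWT", "MKO"))
  pairs <- Filter(function(p) all(p %in% grps), pairs)
  for (p in pairs) {
    a <- calls$per_sample_total[calls$samples$group == p[1]]
    b <- calls$per_sample_total[calls$samples$group == p[2]]
    comparisons[[paste(p, collapse = "_vs_")]] <-
      mann_whitney_groups(a, b, family_size = length(pairs), groups = p,
                          name = "global_mean")
  }
  interval_stats <- list()
  for (p in Filter(function(p) all(p %in% grps),
                   list(c("FWT", "FKO"), c("MWT", "MKO")))) {
    interval_stats[[paste(p, collapse = "_vs_")]] <-
      fisher_intervals(calls, p[1], p[2], max_prop = cfg$interval_cutoff)
  }
  region_stats <- list()
  if (all(c("FWT", "MWT") %in% grps)) {
    for (r in cfg$regions)
      region_stats[[attr(r, "name")]] <- region_compare(calls, r)
  }
  ratio <- tryCatch(size_vs_rate(calls, panel), error = function(e) NA_real_)
  list(calls = calls, chrom_stats = cs, group_means = gmeans,
       comparisons = comparisons, interval_stats = interval_stats,
       region_stats = region_stats, size_ratio_19_vs_1 = ratio)
}

#' Run the full pipeline
#'
#' Simulate (or read) genotypes, apply QC, call crossover events, compute
#' the summary statistics, and write every stage table plus a
#' machine-readable `summary.json` to the output directory.  With
#' `qc$scenario = "both"` the calling and statistics stages run under both
#' missing-call scenarios and the summary reports the bracket.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    xo_abort("`config` must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  panel <- config$panel
  if (is.null(panel) && !is.null(config$panel_path))
    panel <- read_panel(config$panel_path, config$chrom_sizes_path)
  truth <- NULL
  if (!is.null(config$sim)) {
    panel <- panel %||% config$sim$panel
    simres <- simulate_offspring(config$sim)
    gm <- simres$genotypes
    truth <- simres$truth
    write_genotypes(gm, file.path(config$out_dir, "genotypes.tsv"))
    write_truth(truth, file.path(config$out_dir, "truth.tsv"))
  } else {
    gm <- read_genotypes(config$genotypes_path, panel)
  }

  qcres <- run_qc(gm, panel, config$qc)
  write_tsv(qcres$report$dropped_markers, config$out_dir, "qc_dropped_markers.tsv")
  write_tsv(qcres$report$dropped_samples, config$out_dir, "qc_dropped_samples.tsv")

  scenarios <- if (config$qc$scenario == "both") c("conservative", "liberal")
               else config$qc$scenario
  runs <- lapply(scenarios, function(sc)
    run_scenario(qcres$genotypes, qcres$panel, sc, config))
  names(runs) <- scenarios

  main <- runs[[1]]
  write_tsv(main$chrom_stats, config$out_dir, "chrom_stats.tsv")
  write_tsv(main$group_means, config$out_dir, "group_means.tsv")
  write_tsv(data.frame(sample_id = main$calls$samples$sample_id,
                       group = main$calls$samples$group,
                       total = main$calls$per_sample_total),
            config$out_dir, "sample_totals.tsv")
  write_tsv(do.call(rbind, main$comparisons), config$out_dir, "comparisons.tsv")
  if (length(main$interval_stats))
    write_tsv(do.call(rbind, lapply(names(main$interval_stats), function(nm)
      cbind(comparison = nm, main$interval_stats[[nm]]))),
      config$out_dir, "interval_stats.tsv")

  power <- NULL
  if (!is.null(truth)) {
    keep <- truth$sample_id %in% main$calls$samples$sample_id
    power <- detection_power(main$calls, truth[keep, ], qcres$panel)
    write_tsv(data.frame(fraction = power$fraction, n_true = power$n_true,
                         n_called = power$n_called,
                         out_of_span = power$losses$out_of_span,
                         cancelled = power$losses$cancelled,
                         residual = power$losses$residual),
              config$out_dir, "power.tsv")
  }

  ps <- summarize_panel(qcres$panel)
  wt_means <- main$group_means
  sex_avg_wt <- if (all(c("FWT", "MWT") %in% wt_means$group))
    sex_averaged(wt_means$mean[wt_means$group == "FWT"],
                 wt_means$mean[wt_means$group == "MWT"]) else NULL

  summary <- list(
    schema = "xomap/summary/v1",
    seed = config$seed,
    scenario = config$qc$scenario,
    panel = list(per_chrom = ps$per_chrom, genome = ps$genome),
    qc = list(n_markers_dropped = nrow(qcres$report$dropped_markers),
              n_samples_dropped = nrow(qcres$report$dropped_samples),
              n_missing_retained = qcres$report$n_missing_retained),
    chrom_stats = main$chrom_stats,
    group_means = main$group_means,
    sex_averaged_wt = sex_avg_wt,
    grand_total = sum(main$calls$per_sample_total),
    comparisons = do.call(rbind, main$comparisons),
    size_ratio_19_vs_1 = main$size_ratio_19_vs_1,
    region_means = lapply(main$region_stats, `[[`, "means"),
    detection_power = if (!is.null(power))
      list(fraction = power$fraction, losses = power$losses),
    scenario_bracket = if (length(runs) == 2) list(
      conservative_total = sum(runs$conservative$calls$per_sample_total),
      liberal_total = sum(runs$liberal$calls$per_sample_total)))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(summary)
}
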