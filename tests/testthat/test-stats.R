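test_that("Mann-Whitney comparison behaves at its edges and thresholds", {
  same <- mann_whitney_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  expect_false(same$significant)

  zero_var <- mann_whitney_groups(rep(5, 10), rep(5, 12))
  expect_equal(zero_var$p, 1)

  disj <- mann_whitney_groups(1:20, 31:50, family_size = 4)
  expect_lt(disj$p, 1e-6)
  expect_equal(disj$threshold, 0.0125)
  expect_true(disj$significant)
  # oracle: U = 0 for fully disjoint samples; normal approximation p
  u <- sum(outer(1:20, 31:50, ">")) + 0.5 * sum(outer(1:20, 31:50, "=="))
  expect_equal(disj$statistic, u)
  mu <- 20 * 20 / 2; sigma <- sqrt(20 * 20 * 41 / 12)
  p_manual <- 2 * pnorm((u + 0.5 - mu) / sigma)
  expect_equal(disj$p, p_manual, tolerance = 1e-10)

  expect_error(mann_whitney_groups(numeric(0), 1:3), "non-empty")
})

test_that("Agresti-Coull intervals match the published formula exhaustively", {
  ci <- agresti_coull_ci(0, 100)
  expect_equal(ci$lower, 0)
  expect_equal(ci$upper, 0.04441205, tolerance = 1e-6)

  ci_n <- agresti_coull_ci(100, 100)
  expect_equal(ci_n$upper, 1)
  expect_equal(ci_n$lower, 1 - 0.04441205, tolerance = 1e-6)

  ci_half <- agresti_coull_ci(50, 100)
  expect_equal(ci_half$lower + ci_half$upper, 1, tolerance = 1e-12)

  for (n in c(1:15, 30, 50)) for (x in 0:n) {
    got <- agresti_coull_ci(x, n)
    want <- oracle_ac(x, n)
    expect_equal(c(got$lower, got$upper), want, tolerance = 1e-12)
  }
  expect_error(agresti_coull_ci(2, 0), ">= 1")
})

test_that("per-interval Fisher tests agree with hypergeometric enumeration", {
  # spec table: [[20,59],[5,74]] (x/n = 20/79 vs 5/79)
  expect_equal(oracle_fisher_p(20, 79, 5, 79), 0.001809004, tolerance = 1e-6)
  expect_equal(fisher.test(matrix(c(20, 59, 5, 74), 2, byrow = TRUE))$p.value,
               oracle_fisher_p(20, 79, 5, 79), tolerance = 1e-9)

  set.seed(53)
  for (i in 1:40) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    x1 <- rbinom(1, n1, runif(1)); x2 <- rbinom(1, n2, runif(1))
    expect_equal(
      fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE))$p.value,
      oracle_fisher_p(x1, n1, x2, n2), tolerance = 1e-9,
      info = sprintf("%d/%d vs %d/%d", x1, n1, x2, n2))
  }
})

test_that("fisher_intervals derives its Bonferroni family from the data", {
  panel <- ref_panel()
  res <- simulate_offspring(sim_config(panel, c(FWT = 40, FKO = 40),
                                       missing_rate = 0, seed = 59))
  calls <- call_events(res$genotypes, panel)
  ivs <- fisher_intervals(calls, "FWT", "FKO")
  # full panel: 111 intervals x 2 comparisons -> 0.05/222
  expect_equal(nrow(ivs), 111)
  expect_equal(unique(ivs$threshold), 0.05 / 222)
  expect_equal(round(unique(ivs$threshold), 6), 0.000225)
  # identical groups yield p = 1
  same <- fisher_intervals(calls, "FWT", "FWT")
  expect_true(all(same$p_fisher > 1 - 1e-8))
  # p-values match the enumeration oracle interval by interval
  idx <- sample(nrow(ivs), 10)
  for (k in idx)
    expect_equal(ivs$p_fisher[k],
                 oracle_fisher_p(ivs$x_a[k], ivs$n_a[k], ivs$x_b[k],
                                 ivs$n_b[k]),
                 tolerance = 1e-9)
  # the sensitivity cutoff shrinks the family accordingly
  cut <- fisher_intervals(calls, "FWT", "FKO", max_prop = 0.10)
  expect_lt(nrow(cut), nrow(ivs))
  expect_equal(unique(cut$threshold), 0.05 / (2 * nrow(cut)))
})

test_that("null simulations stay below the Bonferroni threshold family-wise", {
  # WT and KO drawn from identical maps: no interval should reach
  # significance after correction (family-wise error control)
  panel <- ref_panel()
  res <- simulate_offspring(sim_config(panel, c(FWT = 79, FKO = 79),
                                       missing_rate = 0, seed = 61))
  calls <- call_events(res$genotypes, panel)
  ivs <- fisher_intervals(calls, "FWT", "FKO")
  expect_false(any(ivs$significant))
})

test_that("region comparisons use the documented interval sets", {
  expect_equal(nrow(centromeric_region()), 6)
  expect_equal(nrow(telomeric_region()), 12)

  panel <- ref_panel()
  res <- simulate_offspring(sim_config(panel, c(FWT = 60, MWT = 60),
                                       missing_rate = 0, seed = 67))
  calls <- call_events(res$genotypes, panel)
  cen <- region_compare(calls, centromeric_region())
  expect_equal(cen$means$n_intervals, c(6, 6))
  expect_equal(dim(cen$proportions), c(6, 2))
  tel <- region_compare(calls, telomeric_region())
  expect_equal(tel$means$n_intervals, c(12, 12))
  # means recompute from the proportions matrix
  expect_equal(cen$means$mean, unname(colMeans(cen$proportions)))

  # a single interval with equal proportions: difference 0, p = 1
  one <- region_spec(1, "first", "one")
  same <- region_compare(calls, one, groups = c("FWT", "FWT"))
  expect_equal(diff(same$means$mean), 0)
  expect_equal(same$comparison$p, 1)

  expect_error(region_compare(calls, region_spec(integer(0), character(0))),
               "empty")
})

test_that("small chromosomes recombine at a higher per-Mbp rate", {
  fix <- callset_from_counts(ref_event_counts(), ref_group_sizes())
  panel <- ref_panel()
  ratio <- size_vs_rate(fix, panel)
  expect_equal(ratio, 2.617, tolerance = 1e-3)
  expect_gte(ratio, 2)
  # identical chromosomes give ratio 1
  expect_equal(size_vs_rate(fix, panel, chrom_a = 5, chrom_b = 5), 1)

  # a simulated genome with flat cM/Mbp: ratio ~ 1 within Monte-Carlo error
  flat_map <- stats::setNames(ref_chrom_sizes() * 0.5, 1:19)  # 0.5 cM/Mbp
  res <- simulate_offspring(sim_config(panel, c(FWT = 150, MWT = 150),
                                       map_female = flat_map,
                                       map_male = flat_map,
                                       missing_rate = 0, seed = 71))
  calls <- call_events(res$genotypes, panel)
  flat_ratio <- size_vs_rate(calls, panel)
  expect_lt(abs(flat_ratio - 1), 0.35)
})

test_that("detection power reports its loss decomposition coherently", {
  panel <- dense_panel(size = 100, step = 1)
  res <- simulate_offspring(sim_config(
    panel, c(FWT = 100), map_female = c("1" = 100), map_male = c("1" = 100),
    missing_rate = 0, seed = 73))
  calls <- call_events(res$genotypes, panel)
  dp <- detection_power(calls, res$truth, panel)
  # dense panel: fraction = 1 - out-of-span share, cancellation negligible
  expect_equal(dp$fraction,
               1 - (dp$losses$out_of_span + dp$losses$cancelled) / dp$n_true,
               tolerance = 1e-12)
  expect_equal(dp$losses$residual, 0)
  # span covers 1-99 of 100 Mbp
  expect_gt(dp$fraction, 0.9)

  empty_truth <- res$truth
  empty_truth$n_xo <- 0L
  empty_truth$xo_bp <- rep(list(numeric(0)), nrow(empty_truth))
  expect_error(detection_power(calls, empty_truth, panel), "undefined")
  expect_error(detection_power(calls, res$truth[1:5, ], panel),
               "different samples")
})

test_that("simulated maps are recovered and sex differences detected", {
  # parameter recovery: dense markers, per-chromosome cM within 3 SE
  panel <- dense_panel(size = 120, step = 2)
  true_cM <- 85
  res <- simulate_offspring(sim_config(
    panel, c(FWT = 250), map_female = c("1" = true_cM),
    map_male = c("1" = true_cM), missing_rate = 0, seed = 79))
  calls <- call_events(res$genotypes, panel)
  tots <- calls$per_sample_total
  est_cM <- 100 * mean(tots)
  se_cM <- 100 * sd(tots) / sqrt(length(tots))
  # the span 2-118 Mbp misses ~3.3% of the map; compare against the
  # within-span expectation
  expect_lt(abs(est_cM - true_cM * (118 - 2) / 120), 3 * se_cM)

  # female > male ordering is recovered when maps differ by >= 10%
  p <- ref_panel()
  res2 <- simulate_offspring(sim_config(
    p, c(FWT = 79, FKO = 79, MWT = 78, MKO = 78),
    map_female = ref_genetic_map("female", 1),
    map_male = ref_genetic_map("male", 1),
    missing_rate = 0, seed = 83))
  calls2 <- call_events(res2$genotypes, p)
  gmn <- group_means(calls2)
  expect_gt(gmn$mean[gmn$group == "FWT"], gmn$mean[gmn$group == "MWT"])
  # qualitative reproduction: significant sex contrast, null genotype contrast
  sex <- mann_whitney_groups(
    calls2$per_sample_total[calls2$samples$group == "FWT"],
    calls2$per_sample_total[calls2$samples$group == "MWT"], family_size = 4)
  geno <- mann_whitney_groups(
    calls2$per_sample_total[calls2$samples$group == "FWT"],
    calls2$per_sample_total[calls2$samples$group == "FKO"], family_size = 4)
  expect_true(sex$significant)
  expect_false(geno$significant)
})
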