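# helper: cohort with controllable per-marker missingness on the tiny panel
qc_cohort <- function(n = 314, miss = list(), het = list(), panel = tiny_panel()) {
  m <- nrow(panel$markers)
  calls <- matrix(rep(c("B", "H"), length.out = n * m), n, m)  # balanced
  colnames(calls) <- panel$markers$marker_id
  for (j in names(het)) {    # set heterozygote count of marker j
    k <- het[[j]]
    calls[, j] <- c(rep("H", k), rep("B", n - k))
  }
  for (j in names(miss)) calls[seq_len(miss[[j]]), j] <- "N"
  genotype_matrix(data.frame(sample_id = sprintf("s%03d", 1:n),
                             group = rep(c("FWT", "MWT"), length.out = n)),
                  calls)
}

test_that("marker call-rate filter is strict at the 95% threshold", {
  # 300/314 called = 95.5% -> retained; 14 missing is fine, 16 is not
  gm <- qc_cohort(miss = list(a1 = 14, a2 = 16))
  res <- filter_markers(gm, tiny_panel())
  expect_false("a1" %in% res$report$marker_id)
  expect_true("a2" %in% res$report$marker_id)
  expect_equal(res$report$reason[res$report$marker_id == "a2"], "low_call")

  # exactly at threshold: 19/20 = 0.95 must be dropped (">" not ">=")
  gm20 <- qc_cohort(n = 20, miss = list(b1 = 1))
  res20 <- filter_markers(gm20, tiny_panel())
  expect_true("b1" %in% res20$report$marker_id)

  # zero non-missing calls -> dropped as low_call with rate 0
  gm0 <- qc_cohort(n = 20, miss = list(a3 = 20))
  res0 <- filter_markers(gm0, tiny_panel())
  row <- res0$report[res0$report$marker_id == "a3", ]
  expect_equal(row$reason, "low_call")
  expect_equal(row$call_rate, 0)
})

test_that("distortion filter applies the exact binomial test after call-rate", {
  # 130 H / 200 calls: two-sided exact p from enumeration, far below 0.01
  p130 <- oracle_binom_p(130, 200)
  expect_lt(p130, 0.01)

  gm <- qc_cohort(n = 200, het = list(a1 = 130, a2 = 100))
  res <- filter_markers(gm, tiny_panel())
  rep <- res$report
  expect_equal(rep$reason[rep$marker_id == "a1"], "distortion")
  expect_equal(rep$p_distortion[rep$marker_id == "a1"], p130,
               tolerance = 1e-10)
  expect_false("a2" %in% rep$marker_id)  # perfectly balanced: p = 1

  # a marker failing BOTH filters is reported once, as low_call
  gm2 <- qc_cohort(n = 200, miss = list(a1 = 20), het = list(a1 = 130))
  rep2 <- filter_markers(gm2, tiny_panel())$report
  expect_equal(rep2$reason[rep2$marker_id == "a1"], "low_call")
})

test_that("sample call-rate filter is strict at the 90% threshold", {
  panel <- ref_panel()
  res <- simulate_offspring(sim_config(panel, c(FWT = 3, MWT = 3),
                                       missing_rate = 0, seed = 8))
  gm <- res$genotypes
  gm$calls[1, 1:12] <- "N"   # 118/130 = 90.8% -> retained
  gm$calls[2, 1:14] <- "N"   # 116/130 = 89.2% -> dropped
  out <- filter_samples(gm)
  expect_equal(out$report$sample_id, gm$samples$sample_id[2])
  expect_equal(nrow(out$genotypes$calls), 5)

  # no missing calls: nobody dropped
  expect_equal(nrow(filter_samples(res$genotypes)$report), 0)
})

test_that("QC is idempotent and dimensions are conserved", {
  gm <- qc_cohort(n = 200, miss = list(a1 = 30, b3 = 12),
                  het = list(a2 = 135))
  gm$calls[1, ] <- "N"  # hopeless sample
  panel <- tiny_panel()
  q1 <- run_qc(gm, panel)
  expect_equal(nrow(q1$report$dropped_markers) + ncol(q1$genotypes$calls),
               ncol(gm$calls))
  expect_equal(nrow(q1$report$dropped_samples) + nrow(q1$genotypes$calls),
               nrow(gm$calls))
  q2 <- run_qc(q1$genotypes, q1$panel)
  expect_identical(q2$genotypes$calls, q1$genotypes$calls)
  expect_equal(nrow(q2$report$dropped_markers), 0)
  expect_equal(nrow(q2$report$dropped_samples), 0)
})

test_that("missing-call scenarios bracket the event count as specified", {
  panel <- tiny_panel()
  # chrom 1 calls B,N,B,B and chrom 2 complete: conservative 0, liberal 2
  gm <- gm_from_rows(list(c("B", "N", "B", "B", "B", "B", "B")), panel)
  cons <- call_events(apply_missing_scenario(gm, panel, "conservative"), panel)
  lib <- call_events(apply_missing_scenario(gm, panel, "liberal"), panel)
  expect_equal(sum(cons$per_sample_total), 0)
  expect_equal(sum(lib$per_sample_total), 2)
  # conservative leaves the two flanking intervals not-assessed
  expect_true(all(is.na(cons$events[1, 1:2])))

  # B,N,H (then H, so the tail adds nothing): one event either way
  gm2 <- gm_from_rows(list(c("B", "N", "H", "H", "B", "B", "B")), panel)
  for (sc in c("conservative", "liberal")) {
    calls <- call_events(apply_missing_scenario(gm2, panel, sc), panel)
    expect_equal(sum(calls$per_sample_total), 1)
  }

  # property: conservative total <= liberal total on noisy simulations
  set.seed(21)
  for (rep in 1:5) {
    res <- simulate_offspring(sim_config(
      ref_panel(), c(FWT = 30, MWT = 30), missing_rate = 0.05,
      seed = 100 + rep))
    p <- ref_panel()
    tc <- call_events(apply_missing_scenario(res$genotypes, p, "conservative"), p)
    tl <- call_events(apply_missing_scenario(res$genotypes, p, "liberal"), p)
    expect_lte(sum(tc$per_sample_total), sum(tl$per_sample_total))
  }

  # with no missing data the scenarios coincide exactly
  res0 <- simulate_offspring(sim_config(ref_panel(), c(FWT = 20, MKO = 20),
                                        missing_rate = 0, seed = 31))
  p <- ref_panel()
  c0 <- call_events(apply_missing_scenario(res0$genotypes, p, "conservative"), p)
  l0 <- call_events(apply_missing_scenario(res0$genotypes, p, "liberal"), p)
  expect_identical(c0$events, l0$events)
})

test_that("distortion filter type-I error matches its analytic size", {
  n <- 314; alpha <- 0.01
  # analytic size of the exact two-sided test at this n
  d <- dbinom(0:n, n, 0.5)
  pvals <- vapply(0:n, function(x) sum(d[d <= d[x + 1] * (1 + 1e-7)]), 0)
  size <- sum(d[pvals < alpha])
  expect_lte(size, alpha)          # exact test never exceeds nominal level
  expect_gt(size, alpha / 3)       # ... but is not absurdly conservative

  set.seed(77)
  m <- 10000
  h <- rbinom(m, n, 0.5)
  rej <- mean(pvals[h + 1] < alpha)
  expect_lt(abs(rej - size), 3 * sqrt(size * (1 - size) / m))

  # and through the filter itself, on a 2000-marker null cohort
  m2 <- 2000
  panel <- marker_panel(
    data.frame(chrom = 1, pos_bp = seq_len(m2) * 1e5,
               marker_id = sprintf("n%04d", seq_len(m2))),
    c("1" = m2 * 0.1 + 1))
  h2 <- rbinom(m2, n, 0.5)
  calls <- vapply(h2, function(k) sample(c(rep("H", k), rep("B", n - k))),
                  character(n))
  colnames(calls) <- panel$markers$marker_id
  gm <- genotype_matrix(data.frame(sample_id = sprintf("s%03d", 1:n),
                                   group = rep("FWT", n)), calls)
  dropped <- filter_markers(gm, panel)$report
  rej2 <- sum(dropped$reason == "distortion") / m2
  expect_lt(abs(rej2 - size), 3 * sqrt(size * (1 - size) / m2) + 1e-9)
})
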