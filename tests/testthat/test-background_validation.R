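test_that("one-sided Fisher p behaves at its extremes", {
  site <- genomic_site("chr1", 100, "A", "T")
  # zero alt reads: the minimum of the one-sided enrichment tail is 1
  tab <- make_counts(c("s1", "s2"), alt = c(0, 3), ref = c(100, 2000))
  expect_equal(fisher_site_test(tab, "s1", site)$p_raw, 1)
  # clear enrichment over a clean deep background
  tab <- make_counts(c("s1", "s2"), alt = c(5, 2), ref = c(95, 2000))
  expect_lt(fisher_site_test(tab, "s1", site)$p_raw, 1e-4)
  # rate-matched foreground is not significant
  tab <- make_counts(c("s1", "s2"), alt = c(1, 10), ref = c(999, 9990))
  expect_gt(fisher_site_test(tab, "s1", site)$p_raw, 0.3)
})

test_that("the vectorised exact p matches fisher.test on random tables", {
  set.seed(31)
  for (i in 1:50) {
    a <- sample(0:30, 1); r <- sample(1:500, 1)
    ba <- sample(0:50, 1); br <- sample(1:5000, 1)
    expect_equal(
      fisher_alt_p(a, r, ba, br),
      fisher.test(matrix(c(a, r, ba, br), 2, byrow = TRUE),
                  alternative = "greater")$p.value,
      tolerance = 1e-12)
  }
})

test_that("adding foreground alt reads never increases the p value", {
  p <- fisher_alt_p(0:40, 1000, 10, 10000)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("empty background pools are an error naming the site", {
  tab <- make_counts("s1", alt = 5, ref = 95)
  expect_error(fisher_site_test(tab, "s1", genomic_site("chr1", 100, "A", "T")),
               "chr1:100")
})

test_that("Holm step-down matches hand-computed values", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(c(1, 1)), c(1, 1))
  expect_equal(holm_adjust(0.37), 0.37)
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(holm_adjust(c(0.1, -0.2)), "0, 1")
})

test_that("Holm adjustment never decreases a p value", {
  set.seed(32)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("a cohort with no alt reads retains nothing after one round", {
  tab <- make_counts(paste0("s", 1:5), alt = rep(0, 5), ref = rep(1000, 5))
  cand <- tab[, c("sample_id", "chrom", "pos", "ref", "alt")]
  out <- iterate_validation(tab, cand)
  expect_equal(nrow(out$retained), 0L)
  expect_equal(max(out$log$iteration), 1L)
  expect_true(all(out$log$p_raw == 1))
})

test_that("a single hot sample among clean ones is retained and carried", {
  tab <- make_counts(paste0("s", 1:30),
                     alt = c(40, rep(0, 29)),
                     ref = c(1960, rep(2000, 29)))
  cand <- tab[, c("sample_id", "chrom", "pos", "ref", "alt")]
  out <- iterate_validation(tab, cand)
  expect_equal(out$retained$sample_id, "s1")
  expect_true(out$retained$carried_forward)
  orc <- oracle_iterate(tab, cand)
  expect_setequal(oracle_pair_key(out$retained), orc$retained)
})

test_that("two samples sharing a true variant are retained in successive rounds", {
  # round 1: s1 dominates; s2 against a background still polluted by s1
  # is not significant.  round 2: with s1 excluded, s2 clears the bar.
  tab <- make_counts(c("s1", "s2", "s3"),
                     alt = c(30, 15, 0), ref = c(970, 985, 2000))
  cand <- tab[tab$sample_id != "s3",
              c("sample_id", "chrom", "pos", "ref", "alt")]
  out <- iterate_validation(tab, cand)
  ret <- out$retained[order(out$retained$sample_id), ]
  expect_equal(ret$sample_id, c("s1", "s2"))
  expect_equal(ret$iteration, c(1L, 2L))
  expect_true(all(ret$carried_forward))
  orc <- oracle_iterate(tab, cand)
  expect_setequal(oracle_pair_key(out$retained), orc$retained)
})

test_that("iterative validation matches the brute-force oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(seed + 400)
    out <- iterate_validation(inst$counts, inst$candidates)
    orc <- oracle_iterate(inst$counts, inst$candidates)
    expect_setequal(oracle_pair_key(out$retained), orc$retained)
    expect_setequal(
      oracle_pair_key(out$results[out$results$carried_forward, ]),
      orc$carried)
  }
})

test_that("matched-normal exclusion removes the normal from the tumor background", {
  # normal shares the tumor variant; with the normal pooled, the tumor
  # fails; excluded, it validates
  tab <- make_counts(c("t1", "n1", "s3", "s4"),
                     alt = c(30, 28, 0, 0), ref = c(970, 972, 2000, 2000))
  cand <- tab[tab$sample_id == "t1",
              c("sample_id", "chrom", "pos", "ref", "alt")]
  pooled <- iterate_validation(tab, cand)
  excl <- iterate_validation(tab, cand, matched = "n1")
  expect_gt(pooled$results$p_adj, excl$results$p_adj)
  expect_true(excl$results$retained)
})

test_that("SNV classification applies the configured depth and p gates", {
  cfg <- pipeline_config()
  expect_equal(classify_snv(150, 0.01, 120, 0.9, cfg)$status, "PASS")
  expect_equal(classify_snv(150, 0.01, 50, NA, cfg)$status, "TUMOR_ONLY")
  expect_equal(classify_snv(99, 0.01, 120, 0.9, cfg)$status, "LOW_DEPTH")
  expect_equal(classify_snv(NA, NA, NA, NA, cfg)$status, "NOT_ASSAYED")
  # boundaries: depth 100 is evaluable; tumor p exactly 0.05 passes;
  # normal p exactly 0.05 is not "> 0.05" and fails
  expect_equal(classify_snv(100, 0.05, 100, 0.051, cfg)$status, "PASS")
  expect_equal(classify_snv(100, 0.05, 100, 0.05, cfg)$status, "FAIL")
  expect_equal(classify_snv(100, 0.051, 100, 0.9, cfg)$status, "FAIL")
  expect_equal(classify_snv(100, 0.05, 99, NA, cfg)$status, "TUMOR_ONLY")
  expect_equal(classify_snv(100, 0.051, 99, NA, cfg)$status, "FAIL")
})

test_that("cohort-level SNV validation recovers a spiked variant end to end", {
  sim0 <- simulate_cohort_counts(n_pairs = 6, n_sites = 40,
                                 mean_depth = c(2000, 2000), seed = 51)
  sp <- spike_spec("P03_T", sim0$sites[7, ], true_vaf = 0.05)
  sim <- simulate_cohort_counts(n_pairs = 6, n_sites = 40,
                                mean_depth = c(2000, 2000), spikes = sp,
                                seed = 51)
  counts <- rbind(sim$tumor, sim$normal)
  cand <- sp[, c("sample_id", "chrom", "pos", "ref", "alt")]
  res <- validate_snv_cohort(counts, cand, sim$meta)
  expect_equal(res$outcomes$status, "PASS")
  expect_equal(res$outcomes$normal_sample, "P03_N")
  expect_lte(res$outcomes$tumor_p_adj, 0.05)
  expect_gt(res$outcomes$normal_p_adj, 0.05)
})
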