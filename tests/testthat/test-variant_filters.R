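cfg <- pipeline_config()

test_that("paired indel validation applies the protocol rules", {
  d <- validate_indel(10, 2, 10, 0, config = cfg)
  expect_equal(d$status, "PASS")
  expect_length(d$failed_rules, 0L)
  # "> 1 consensus tumor read": exactly 1 fails
  d <- validate_indel(10, 1, 10, 0, config = cfg)
  expect_equal(d$status, "FAIL")
  expect_true("indel.min_tumor_alt" %in% d$failed_rules)
})

test_that("paired indel boundaries match the strict inequalities", {
  # depth "> 5": 5 fails, 6 passes (tumor side; normal evaluable)
  expect_equal(validate_indel(5, 2, 10, 0, config = cfg)$status, "FAIL")
  expect_equal(validate_indel(6, 2, 10, 0, config = cfg)$status, "PASS")
  # "< 20 consensus normal reads": 20 fails, 19 passes
  expect_equal(validate_indel(100, 10, 100, 20, config = cfg)$status, "FAIL")
  expect_equal(validate_indel(100, 10, 100, 19,
                              normal_vaf = 0.04, config = cfg)$status, "PASS")
  # tumor VAF "> 0.01%": exactly 0.0001 fails
  expect_equal(validate_indel(10000, 2, 100, 0, tumor_vaf = 1e-4,
                              config = cfg)$status, "FAIL")
  expect_equal(validate_indel(10000, 2, 100, 0, tumor_vaf = 1.1e-4,
                              config = cfg)$status, "PASS")
  # normal VAF "< 5%": exactly 0.05 fails
  expect_equal(validate_indel(100, 5, 100, 5, normal_vaf = 0.05,
                              config = cfg)$status, "FAIL")
  expect_equal(validate_indel(100, 5, 100, 4, normal_vaf = 0.04,
                              config = cfg)$status, "PASS")
})

test_that("the tumor-only indel path engages when the normal lacks depth", {
  # normal depth 3 is not evaluable; 1 tumor read suffices
  d <- validate_indel(10, 1, 3, 0, config = cfg)
  expect_equal(d$status, "TUMOR_ONLY")
  # tumor-only depth reads "5 consensus reads" as >= 5
  expect_equal(validate_indel(5, 1, 3, 0, config = cfg)$status, "TUMOR_ONLY")
  expect_equal(validate_indel(4, 1, 3, 0, config = cfg)$status, "FAIL")
  expect_equal(validate_indel(10, 0, 3, 0, config = cfg)$status, "FAIL")
  # absent normal uses the same path
  expect_equal(validate_indel(10, 1, config = cfg)$status, "TUMOR_ONLY")
  # both depth readings are switchable
  strict <- pipeline_config(indel = indel_rules(tumor_only_depth_strict = TRUE,
                                                paired_depth_strict = FALSE))
  expect_equal(validate_indel(5, 1, 3, 0, config = strict)$status, "FAIL")
  expect_equal(validate_indel(5, 2, 5, 0, config = strict)$status, "PASS")
  expect_equal(validate_indel(NA, NA, config = cfg)$status, "NOT_EVALUABLE")
})

test_that("de novo filtering applies all six rules at their exact boundaries", {
  expect_equal(filter_denovo(200, 3, 0.015, 150, 0, 0, cfg)$status, "PASS")
  # depth >= 5 on both sides: 4 fails, 5 passes
  expect_equal(filter_denovo(4, 3, 0.015, 150, 0, 0, cfg)$status, "FAIL")
  expect_equal(filter_denovo(5, 3, 0.015, 150, 0, 0, cfg)$status, "PASS")
  expect_equal(filter_denovo(200, 3, 0.015, 4, 0, 0, cfg)$status, "FAIL")
  expect_equal(filter_denovo(200, 3, 0.015, 5, 0, 0, cfg)$status, "PASS")
  # tumor VAF > 0.5%: 0.004 and exactly 0.005 fail, 0.0051 passes
  d <- filter_denovo(200, 3, 0.004, 150, 0, 0, cfg)
  expect_equal(d$status, "FAIL")
  expect_equal(d$failed_rules, "denovo.min_tumor_vaf")
  expect_equal(filter_denovo(200, 3, 0.005, 150, 0, 0, cfg)$status, "FAIL")
  expect_equal(filter_denovo(200, 3, 0.0051, 150, 0, 0, cfg)$status, "PASS")
  # normal VAF < 5%: exactly 0.05 fails
  expect_equal(filter_denovo(200, 3, 0.015, 150, 0, 0.05, cfg)$status, "FAIL")
  expect_equal(filter_denovo(200, 3, 0.015, 150, 0, 0.049, cfg)$status, "PASS")
  # < 5 normal supporting reads: 5 fails, 4 passes
  d <- filter_denovo(200, 3, 0.015, 150, 5, 0.01, cfg)
  expect_equal(d$status, "FAIL")
  expect_true("denovo.max_normal_alt" %in% d$failed_rules)
  expect_equal(filter_denovo(200, 3, 0.015, 150, 4, 0.01, cfg)$status, "PASS")
  # >= 2 tumor supporting reads: 1 fails, 2 passes
  expect_equal(filter_denovo(200, 1, 0.015, 150, 0, 0, cfg)$status, "FAIL")
  expect_equal(filter_denovo(200, 2, 0.015, 150, 0, 0, cfg)$status, "PASS")
  expect_equal(filter_denovo(200, NA, 0.015, 150, 0, 0, cfg)$status,
               "NOT_EVALUABLE")
})

test_that("filter decisions are pure and fully explained", {
  d1 <- filter_denovo(4, 1, 0.004, 4, 5, 0.06, cfg)
  d2 <- filter_denovo(4, 1, 0.004, 4, 5, 0.06, cfg)
  expect_identical(d1, d2)
  expect_setequal(d1$failed_rules,
                  c("denovo.min_depth.tumor", "denovo.min_depth.normal",
                    "denovo.max_normal_vaf", "denovo.min_tumor_vaf",
                    "denovo.max_normal_alt", "denovo.min_tumor_alt"))
})

test_that("consequence filtering keeps protein-altering classes", {
  v <- variant_calls(genomic_site("chr1", 1:4, "A", "T"), "s1",
                     consequence = c("missense", "synonymous",
                                     "intergenic", "frameshift"))
  kept <- filter_consequence(v)
  expect_setequal(kept$consequence, c("missense", "frameshift"))
  v2 <- variant_calls(genomic_site("chr1", 1, "A", "T"), "s1",
                      consequence = "weird_term")
  expect_warning(out <- filter_consequence(v2), "unrecognised")
  expect_equal(nrow(out), 0L)
})

test_that("known-variant removal matches on the full (sample, allele) key", {
  v <- variant_calls(genomic_site("chr1", c(10, 10, 20), "A",
                                  c("T", "G", "T")), "s1")
  known <- v[1, ]
  out <- remove_known(v, known)
  expect_equal(nrow(out), 2L)
  # same site, different alt survives
  expect_true(any(out$pos == 10 & out$alt == "G"))
  expect_identical(remove_known(v, known[0, ]), v)
  # a different sample's identical allele is not removed
  other <- v[1, ]; other$sample_id <- "s2"
  expect_equal(nrow(remove_known(v, other)), 3L)
})

test_that("allowlisted variants are rescued after filtering", {
  v <- variant_calls(genomic_site("chr1", c(10, 20), "A", "T"), "s1",
                     consequence = c("synonymous", "missense"))
  kept <- filter_consequence(v)
  expect_equal(kept$pos, 20)
  rescued <- apply_allowlist(kept, v, v[1, c("sample_id", "chrom", "pos",
                                             "ref", "alt")])
  expect_setequal(rescued$pos, c(10, 20))
})
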