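test_that("motif scanning finds WRC and GYW anchor positions", {
  expect_equal(scan_motifs("AACGTT")$motif_positions, c(3L, 4L))
  expect_equal(scan_motifs("TGCA")$motif_positions, c(2L, 3L))
  expect_equal(scan_motifs("AAAAAA")$motif_positions, integer(0))
  expect_equal(scan_motifs("AT")$motif_positions, integer(0))
  # N never matches a degenerate base
  expect_equal(scan_motifs("NACGTT")$motif_positions, 4L)
  expect_equal(scan_motifs("NNCGNN")$motif_positions, integer(0))
})

test_that("motif scanning agrees with a sliding-window oracle", {
  set.seed(61)
  for (i in 1:30) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(3:120, 1),
                      replace = TRUE), collapse = "")
    expect_equal(scan_motifs(s)$motif_positions, oracle_scan(s), info = s)
  }
})

test_that("scanning is strand-symmetric", {
  set.seed(62)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
               collapse = "")
    fwd <- scan_motifs(s)$motif_positions
    rev_ <- scan_motifs(oracle_revcomp(s))$motif_positions
    expect_equal(sort(81L - rev_), fwd)
  }
})

test_that("motif hit counting validates positions and counts duplicates", {
  idx <- scan_motifs("AACGTT")
  expect_equal(count_motif_hits(c(3, 4), idx), 2L)
  expect_equal(count_motif_hits(1, idx), 0L)
  expect_equal(count_motif_hits(integer(0), idx), 0L)
  expect_equal(count_motif_hits(c(3, 3), idx), 2L)
  expect_error(count_motif_hits(7, idx), "outside")
  expect_error(count_motif_hits(0, idx), "outside")
})

test_that("placement spaces restrict the motif fraction", {
  idx <- scan_motifs("AACGTT")                 # motifs at 3, 4
  expect_equal(idx$motif_fraction, 2 / 6)
  sub <- scan_motifs("AACGTT", placement_space = c(1, 2, 3))
  expect_equal(sub$motif_fraction, 1 / 3)
  expect_error(scan_motifs("AACGTT", placement_space = 7), "outside")
})

test_that("permutation test handles degenerate observations", {
  g <- simulate_gene_with_motifs(400, 0.2, seed = 63)
  idx <- scan_motifs(g)
  r <- permutation_test(idx, n_mut = 5, observed = 0, n_perm = 200,
                        seed = 1)
  expect_equal(r$p_empirical, 1)   # every replicate has >= 0 hits
  # impossible event on a motif-free sequence
  idx0 <- scan_motifs(simulate_gene_with_motifs(100, 0, seed = 64))
  r0 <- permutation_test(idx0, n_mut = 3, observed = 1, n_perm = 500,
                         seed = 2)
  expect_equal(r0$count_ge, 0L)
  expect_equal(r0$p_empirical, 0)
  expect_error(permutation_test(idx, n_mut = 3, observed = 4), "exceed")
  # the add-one estimator never reports exactly zero
  r1 <- permutation_test(idx0, n_mut = 3, observed = 1, n_perm = 500,
                         seed = 2, estimator = "plus_one")
  expect_equal(r1$p_empirical, 1 / 501)
})

test_that("simulated mean hit count matches the analytic expectation", {
  g <- simulate_gene_with_motifs(1000, 0.2, seed = 65)
  idx <- scan_motifs(g)
  f <- idx$motif_fraction
  n_mut <- 19L
  r <- permutation_test(idx, n_mut, observed = 19, n_perm = 20000L,
                        seed = 3)
  # hypergeometric mean and variance of hits under uniform placement
  N <- length(idx$placement_space)
  v <- n_mut * f * (1 - f) * (N - n_mut) / (N - 1)
  se <- sqrt(v / r$n_perm)
  expect_lt(abs(r$mean_sim - n_mut * f), 3 * se)
})

test_that("permutation results are reproducible given a seed", {
  g <- simulate_gene_with_motifs(500, 0.15, seed = 66)
  idx <- scan_motifs(g)
  a <- permutation_test(idx, 10, 4, n_perm = 2000, seed = 9)
  b <- permutation_test(idx, 10, 4, n_perm = 2000, seed = 9)
  expect_identical(a, b)
})

test_that("the C:G-restricted mode only places on C/G positions", {
  g <- simulate_gene_with_motifs(500, 0.2, seed = 67)
  idx <- scan_motifs(g)
  n_cg <- sum(strsplit(g, "")[[1]] %in% c("C", "G"))
  expect_error(permutation_test(idx, n_cg + 1, 0, n_perm = 10,
                                cg_only = TRUE), "placement space")
  r <- permutation_test(idx, min(10, n_cg), 0, n_perm = 100, seed = 1,
                        cg_only = TRUE)
  expect_equal(r$p_empirical, 1)
})

test_that("cohort-total expectation is the sum of per-gene expectations", {
  g1 <- simulate_gene_with_motifs(800, 0.1, seed = 68)
  g2 <- simulate_gene_with_motifs(800, 0.3, seed = 69)
  idx <- list(a = scan_motifs(g1, gene = "a"),
              b = scan_motifs(g2, gene = "b"))
  exp_total <- 10 * idx$a$motif_fraction + 10 * idx$b$motif_fraction
  r <- cohort_total_test(idx, c(a = 10, b = 10), observed_total = 20,
                         n_perm = 20000, seed = 4)
  expect_lt(abs(r$mean_sim - exp_total), 0.15)
  r0 <- cohort_total_test(idx, c(a = 10, b = 10), observed_total = 0,
                          n_perm = 100, seed = 6)
  expect_equal(r0$p_empirical, 1)
})

test_that("a single-gene cohort test reduces to the per-gene test", {
  g <- simulate_gene_with_motifs(600, 0.2, seed = 70)
  idx <- scan_motifs(g, gene = "g")
  single <- permutation_test(idx, 8, 5, n_perm = 3000, seed = 11)
  total <- cohort_total_test(list(g = idx), c(g = 8), observed_total = 5,
                             n_perm = 3000, seed = 11)
  expect_equal(total$count_ge, single$count_ge)
  expect_equal(total$mean_sim, single$mean_sim)
})

test_that("biased mutation placement is usually detected as enrichment", {
  g <- simulate_gene_with_motifs(1000, 0.2, seed = 71)
  idx <- scan_motifs(g)
  p <- vapply(1:30, function(i) {
    mut <- simulate_aid_mutations(g, 19, motif_bias = 5, seed = 700 + i)
    obs <- count_motif_hits(mut, idx)
    permutation_test(idx, 19, obs, n_perm = 2000, seed = 800 + i)$p_empirical
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.8)
})

test_that("FASTA gene sequences feed the scanner", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">SOCS1 some description", "AACGTT", ">IGLL5", "TGCA"), path)
  seqs <- read_gene_fasta(path)
  expect_equal(names(seqs), c("SOCS1", "IGLL5"))
  expect_equal(scan_motifs(seqs[["SOCS1"]])$motif_positions, c(3L, 4L))
})
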