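# umivalid

Validation of ultra-low-frequency somatic variants from UMI
error-corrected deep sequencing.

## The problem

In some tumors the malignant population is a small minority of the
biopsy. The classic case is classical Hodgkin lymphoma, where the
Hodgkin/Reed-Sternberg (HRS) cells typically make up less than 5% of
the tumor mass and sit inside a dense non-neoplastic infiltrate. Bulk
sequencing of such a biopsy surfaces true somatic variants at allele
fractions of roughly 0.5%–25% — squarely inside the error band of
standard sequencing — so every candidate variant needs two layers of
error control before it can be believed:

1. **Molecular error correction.** Reads carrying the same unique
   molecular identifier (UMI) and alignment start derive from one
   original DNA molecule. Collapsing each such read family into a
   single consensus read (families of fewer than 3 reads are dropped;
   reads with mapping quality < 10 or more than 5 mismatches are
   excluded first) removes independent sequencing errors.
2. **Statistical validation against the cohort's own noise floor.**
   For a candidate variant in sample *s* at site *i*, the consensus
   alt/ref counts of *s* are compared by a one-sided Fisher exact test
   against the pooled alt/ref counts of **all other samples** at the
   same site — an empirical, position-specific background error model.
   Each testing round is Holm-corrected; sites with adjusted
   *p* < 0.1 are retained, **excluded from the background pool**, and
   the procedure repeats until a round retains nothing, so real
   variants shared across samples cannot inflate the estimated noise.
   Retained sites with adjusted *p* ≤ 0.05 are carried forward, then
   classified PASS / TUMOR_ONLY / FAIL / LOW_DEPTH against 100×
   depth gates in tumor and matched normal.

Formally, with foreground counts (a_s, r_s) and pooled background
(a_b, r_b), the per-site statistic is the hypergeometric tail

  p = P(X ≥ a_s),  X ~ Hypergeom(a_s + a_b, r_s + r_b, a_s + r_s),

i.e. Fisher's exact test one-sided toward variant enrichment.

Around this core the package provides: deterministic rule engines for
consensus-count indel validation and de novo low-VAF variant filtering
(with every threshold kept in one auditable
`pipeline_config()`); a random-placement permutation test for
enrichment of mutations in AID WRC/GYW hotspot motifs (W = A/T,
R = A/G, Y = C/T; the motif position is the C of WRC or the G of GYW);
EBV positivity calling from competitive-alignment read summaries
(≥ 2 reads at MAPQ ≥ 60); cohort burden and gene co-occurrence
statistics; and a synthetic-data generator that reproduces the
statistical structure of a tumor/normal deep amplicon panel so every
stage can be exercised and calibrated without controlled patient data.

## Worked example

Simulate a 10-pair cohort assayed at 200 sites, spike a single true
variant at 4% VAF into one tumor, and validate it end to end:

```r
library(umivalid)

sites <- panel_sites(200)
sp    <- spike_spec("P05_T", sites[37, ], true_vaf = 0.04)
sim   <- simulate_cohort_counts(n_pairs = 10, n_sites = 200,
                                spikes = sp, seed = 42)
counts <- rbind(sim$tumor, sim$normal)
res <- validate_snv_cohort(counts,
                           sp[, c("sample_id", "chrom", "pos", "ref", "alt")],
                           sim$meta)
res$outcomes
#>   sample_id chrom pos ref alt normal_sample status tumor_depth   tumor_p_adj
#> 1     P05_T  chr1 370   A   G         P05_N   PASS        5077 2.716528e-181
#>   normal_depth normal_p_adj
#> 1         2204            1
```

The spiked variant PASSes: its tumor counts are far above the pooled
background of the other 19 samples, while its matched normal is
indistinguishable from noise (adjusted p = 1). The underlying 2×2
table is visible directly:

```r
fisher_site_test(counts, "P05_T", sites[37, ])
#> Fisher background test: P05_T @ chr1:370:A:G
#>            alt   ref
#> foreground 207  4870
#> background  45 58855
#>   one-sided p = 1.358e-181
```

The AID motif machinery works the same way on synthetic genes:

```r
gene <- simulate_gene_with_motifs(1000, 0.2, seed = 7)
idx  <- scan_motifs(gene, gene = "synthetic")
mut  <- simulate_aid_mutations(gene, n_mut = 19, motif_bias = 5, seed = 8)
permutation_test(idx, n_mut = 19,
                 observed = count_motif_hits(mut, idx),
                 n_perm = 100000, seed = 9)
#> AID motif permutation test [synthetic]
#>   observed 11/19 mutations in WRC/GYW motifs; simulated mean 3.70
#>   11/100000 replicates >= observed; empirical p = 0.00011
```

11 of 19 mutations fall in motifs where uniform placement would put
about 3.7 — the placement bias is detected at p ≈ 1e-4.

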