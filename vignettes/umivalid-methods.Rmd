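---
title: "Methods: validating ultra-low-VAF somatic variants with umivalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating ultra-low-VAF somatic variants with umivalid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umivalid)
```

## Scope and model

`umivalid` addresses variant discovery and validation when true somatic
variants sit at allele fractions (0.5%–25%) overlapping the sequencing
error rate, as happens when the malignant cells — e.g. the
Hodgkin/Reed-Sternberg cells of classical Hodgkin lymphoma — are a
small minority of a bulk biopsy. Two independent error-control layers
are modeled.

### UMI consensus error correction

Reads sharing a unique molecular identifier and alignment start are
treated as copies of one source molecule. After excluding reads with
mapping quality below 10 or more than 5 mismatches, families of fewer
than 3 reads are removed; surviving families are collapsed
position-wise by **unique plurality**: the single most frequent base
among A/C/G/T member calls wins, and any tie yields `N`. `N` calls are
excluded from all downstream allele counts (they contribute to neither
allele nor depth). This rule is conservative — it can abstain but
never invents an allele — and deliberately ignores base qualities,
since family concordance rather than per-base quality is the operative
evidence after PCR amplification. Duplex (strand-aware) consensus and
indel-aware realignment inside families are out of scope.

### Iterative background-noise validation

For candidate pair (sample $s$, site $i$) with consensus counts
$(a_s, r_s)$ and pooled counts $(a_b, r_b)$ over all *other* samples
at $i$, the statistic is the one-sided Fisher exact (hypergeometric
tail) p-value

$$p = P(X \ge a_s), \qquad
  X \sim \mathrm{Hypergeom}(a_s + a_b,\; r_s + r_b,\; a_s + r_s).$$

One-sidedness is a design choice: the alternative of interest is
enrichment *above* the background noise floor, and a depleted
foreground is never evidence for a variant. Each round's p-values are
Holm-adjusted as **one family — every test performed in that round,
across samples and sites**; pairs with adjusted $p < 0.1$ are
retained, excluded from subsequent background pools (only those pairs,
not their whole samples, preserving background depth), and rounds
repeat until one retains nothing. The procedure terminates because the
retained set grows strictly and is bounded by the candidate list.
Retained pairs whose adjusted p (from their retention round) is
$\le 0.05$ are carried forward. We read the carry-forward threshold as
$\le$; and because a never-retained pair necessarily has adjusted
$p \ge 0.1$, carried-forward = retained ∧ $p_{adj} \le 0.05$ is
equivalent to thresholding each candidate's definitive p. The full
per-round log is returned so the alternative reading (a single final
Holm pass after convergence) can be audited from the same output.

Classification then applies depth gates: tumor error-corrected depth
$\ge 100$ reads is required at all (`LOW_DEPTH` otherwise); with an
evaluable normal (depth $\ge 100$ — we reuse the stated tumor gate
because "sufficient normal data" is otherwise undefined), `PASS`
requires tumor $p_{adj} \le 0.05$ **and** normal $p_{adj} > 0.05$;
without an evaluable normal, `TUMOR_ONLY` requires the tumor gate
alone. The matched normal is pooled into its tumor's background by
default (the background is "all other samples");
`pipeline_config(exclude_matched_normal = TRUE)` switches to a pool
that omits it, which matters when a variant contaminates the normal
(see the test on matched-normal exclusion).

Degenerate inputs: a site assayed in fewer than two samples is an
error up front; a background pool that *empties mid-iteration*
(because every other sample's pair was retained) scores $p = 1$ — no
evidence rather than an error, since the situation arises legitimately
on tiny cohorts.

### Rule engines

Indel and de novo filters are pure functions from consensus counts to
a decision plus the list of failed rules; every constant lives in
`pipeline_config()`. The indel rule set mixes a strict paired
depth bound ("> 5 consensus reads") with a bare tumor-only bound
("5 consensus reads", read as $\ge 5$); both readings are encoded and
switchable (`paired_depth_strict`, `tumor_only_depth_strict`) because
the intended strictness at the boundary is ambiguous. All other
inequalities are strict or inclusive exactly as configured and are pinned on both sides
of each boundary by the test suite.

### AID WRC/GYW motif enrichment

The canonical AID hotspot is scanned with IUPAC matching (`WRC` /
`GYW`, W = A/T, R = A/G, Y = C/T; `N` never matches); the motif
position is the C of a WRC match or the G of a GYW match, counted once
when overlapping. Scanning is strand-symmetric by construction since
GYW is the reverse-complement image of WRC. The permutation test
places `n_mut` distinct positions uniformly (without replacement) over
a placement space and counts motif hits; the empirical p is
`count_ge / n_perm` (the never-zero `(count_ge + 1)/(n_perm + 1)`
estimator is available by flag). Design choices here were genuinely
open: the placement distribution is uniform over the space because
nothing finer is specified; the space defaults to the full sequence
but can be restricted by intervals (assayed regions) or to C/G
positions (`cg_only`), emulating placement of C:G substitutions only.
Reproducing per-gene results from a real cohort would require each gene's
actual assayed space, which is not recoverable; the package therefore
treats the space as an explicit input. The cohort-total test places
each gene's count independently and sums hits, so its expectation is
the sum of per-gene expectations (`n_mut` × motif fraction).

### Cohort statistics

EBV positivity requires at least 2 reads labeled EBV at mapping
quality $\ge 60$ ("MQ60" is read as $\ge$, 60 being the aligner
maximum). The burden comparison is Student's equal-variance two-sided
t test by default with a Welch flag, since the protocol fixes only the
two-tailedness; two degenerate conventions are adopted: both
groups constant and equal gives $p = 1$, both constant and unequal is
an error. Co-occurrence runs a two-sided Fisher exact test per
unordered gene pair with Benjamini–Hochberg adjustment across all
pairs (the conventional FDR method for this analysis); direction is
read off the odds ratio.

## Synthetic data generator

The generator produces every input the pipeline consumes, with the
statistical structure the validation test assumes:

* **Depths**: negative binomial around the arm mean (defaults 3,971×
  tumor / 2,168× normal — the error-corrected medians of the kind of
  deep amplicon experiment emulated), clipped at 1, `size = 20`,
  because capture coverage is uneven rather than Poisson.
* **Background error**: per-site rate (default $10^{-3}$, a realistic
  post-consensus amplicon error floor) with optional between-sample
  overdispersion. `dispersion` is a true overdispersion parameter:
  `0` degenerates to pure binomial sampling (the calibration tests
  rely on this), and for `dispersion > 0` per-sample rates are drawn
  from a beta with mean `rate` and concentration `1/dispersion`.
* **Spikes**: true variants add binomial(depth, VAF) supporting reads;
  the spike constructor bounds VAF at 0.25 by default, the upper end
  of the observed low-VAF range, overridable for degenerate tests.
* **Panel sites** are deterministic (`panel_sites()`) so spike
  specifications compose across seeds.
* **Read families and genes**: families flip each base independently
  at a given error rate; synthetic genes reach a target WRC/GYW motif
  density within ±0.02 by planting motif trinucleotides on an A/T
  background, and `simulate_aid_mutations()` places mutations with a
  configurable motif bias as a positive control.

Each generator seeds R's RNG once per call, so identical seeds give
identical outputs and partial reruns are reproducible.

What the generator does **not** emulate: raw FASTQ and alignment
artifacts, strand bias, position-in-read or trinucleotide-specific
error, the gene-level mutation spectrum of any real cohort, or
full-exome scale. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under its stated
assumptions — not that those assumptions exhaust real data, where the
empirical pooling absorbs (but cannot be proven here to absorb)
context-specific error.

## Problem sizes and calibration checks

The test suite exercises, among others:

* equivalence of the iterative validation with a from-scratch
  brute-force re-implementation on 200 randomized instances (≤ 5
  samples × ≤ 12 sites, counts ≤ 50);
* a spike-recovery cohort of 30 pairs × 500 sites at depth 2,000 with
  50 spikes at VAF 0.02 (sensitivity ≥ 0.95) and 100 spike-free
  replicates (≤ 10% carry forward any false site — Holm controls the
  familywise error within each round at 0.05, and the small
  multi-round inflation is bounded empirically);
* 10,000 UMI families at 5% raw error, family sizes 5–9 (consensus
  error well below raw);
* permutation calibration at `n_perm` = 100,000 (simulated mean within
  3 Monte-Carlo SE of the hypergeometric mean), super-uniformity of
  the null empirical p (the p is discrete, hence conservative rather
  than exactly uniform), and ≥ 90% power at a 5× placement bias.

These sizes were chosen as the smallest that make the calibration
statements statistically meaningful; `scripts/acceptance.R` re-runs
the same computations from a single `--seed` and writes the resulting
quantities as JSON.

## Known limitations

* The consensus caller is substitution-only at the voting stage;
  indels are handled downstream on consensus counts, not re-aligned
  within families.
* `read_tagged_sam()` assumes soft-clip-free amplicon alignments (the
  base string is anchored at the alignment start).
* The Fisher background model conditions on the observed margins and
  assumes other samples share the site's error process; systematic
  batch differences between samples would violate this and are not
  modeled.
* Empirical p-values are bounded below by `1/n_perm`; genuinely
  smaller tail probabilities are reported as 0 under the default
  estimator (use `estimator = "plus_one"` for a strictly positive
  bound).
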