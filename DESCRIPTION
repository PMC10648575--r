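Package: umivalid
Title: Validation of Ultra-Low-Frequency Somatic Variants from UMI
    Error-Corrected Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for discovering and validating somatic variants present
    at very low allele fractions in bulk tumor sequencing, as arises when
    the malignant population (for example Hodgkin/Reed-Sternberg cells) is
    a small minority of the biopsy.  Implements collapsing of unique
    molecular identifier (UMI) read families into error-corrected
    consensus reads; an iterative per-site Fisher exact test of each
    sample's variant-supporting reads against the pooled background of all
    other samples, with Holm correction and fixpoint re-estimation of the
    background; deterministic rule engines for indel and de novo low-VAF
    variant filtering; a permutation test for enrichment of mutations in
    AID (activation-induced cytidine deaminase) WRC/GYW hotspot motifs;
    Epstein-Barr virus positivity calling from competitive-alignment read
    summaries; and cohort-level burden and co-occurrence statistics.  A
    synthetic-data generator reproduces the statistical structure of
    tumor/normal deep amplicon panels so every stage can be exercised and
    calibrated without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
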