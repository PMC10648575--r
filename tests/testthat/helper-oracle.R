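# Independent oracles, deliberately implemented differently from the
# package: per-candidate loops with stats::fisher.test, sliding-window
# motif matching, closed-form t.  Used to cross-check the vectorised
# implementation paths.

oracle_pair_key <- function(d) {
  paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt, sep = ":")
}
oracle_site_key <- function(d) {
  paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
}

# brute-force iterative background validation: every round recomputed
# from scratch with fisher.test
oracle_iterate <- function(counts, candidates, retain_alpha = 0.1,
                           final_alpha = 0.05) {
  retained <- character(0)
  retained_p <- numeric(0)
  repeat {
    act <- candidates[!(oracle_pair_key(candidates) %in% retained), ,
                      drop = FALSE]
    if (nrow(act) == 0L) break
    p <- vapply(seq_len(nrow(act)), function(i) {
      cand <- act[i, ]
      at <- counts[oracle_site_key(counts) == oracle_site_key(cand), ,
                   drop = FALSE]
      fg <- at[at$sample_id == cand$sample_id, , drop = FALSE]
      bg <- at[at$sample_id != cand$sample_id &
                 !(oracle_pair_key(at) %in% retained), , drop = FALSE]
      ba <- sum(bg$alt_count); br <- sum(bg$ref_count)
      if (ba + br == 0) return(1)
      stats::fisher.test(matrix(c(fg$alt_count, fg$ref_count, ba, br),
                                nrow = 2, byrow = TRUE),
                         alternative = "greater")$p.value
    }, numeric(1))
    padj <- stats::p.adjust(p, method = "holm")
    hit <- padj < retain_alpha
    if (!any(hit)) break
    retained <- c(retained, oracle_pair_key(act)[hit])
    retained_p <- c(retained_p, padj[hit])
  }
  list(retained = retained, carried = retained[retained_p <= final_alpha])
}

# sliding-window WRC/GYW scanner with explicit degenerate-base sets
oracle_scan <- function(seq_chr) {
  chars <- strsplit(toupper(seq_chr), "")[[1]]
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  n <- length(chars)
  pos <- integer(0)
  for (p in seq_len(n)) {
    if (p >= 3 && chars[p] == "C" &&
        chars[p - 2] %in% W && chars[p - 1] %in% R)
      pos <- c(pos, p)
    if (p <= n - 2 && chars[p] == "G" &&
        chars[p + 1] %in% Y && chars[p + 2] %in% W)
      pos <- c(pos, p)
  }
  sort(unique(pos))
}

oracle_revcomp <- function(seq_chr) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(seq_chr), "")[[1]]]), collapse = "")
}

# closed-form equal-variance two-sample t
oracle_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = nx + ny - 2))
}

# random small validation instance: full sample x site count grid with
# bounded counts plus a random candidate subset
random_instance <- function(seed, max_samples = 5L, max_sites = 12L,
                            max_count = 50L) {
  set.seed(seed)
  ns <- sample(2:max_samples, 1L)
  nt <- sample(1:max_sites, 1L)
  samples <- paste0("s", seq_len(ns))
  grid <- expand.grid(sample_id = samples, pos = seq_len(nt) * 5L,
                      stringsAsFactors = FALSE)
  grid$chrom <- "chr1"; grid$ref <- "A"; grid$alt <- "T"
  grid$ref_count <- sample(0:max_count, nrow(grid), replace = TRUE)
  grid$alt_count <- sample(0:8, nrow(grid), replace = TRUE)
  counts <- site_count_table(grid[, c("sample_id", "chrom", "pos", "ref",
                                      "alt", "ref_count", "alt_count")])
  pick <- runif(nrow(counts)) < 0.4
  if (!any(pick)) pick[sample.int(nrow(counts), 1L)] <- TRUE
  cand <- counts[pick, c("sample_id", "chrom", "pos", "ref", "alt")]
  rownames(cand) <- NULL
  list(counts = counts, candidates = cand)
}
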