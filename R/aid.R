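#' Scan a sequence for AID WRC/GYW hotspot motifs
#'
#' The canonical AID (activation-induced cytidine deaminase)
#' somatic-hypermutation hotspot is a cytosine preceded by W (A/T) then
#' R (A/G); its reverse-complement image is a guanine followed by
#' Y (C/T) then W (A/T).  A motif position is the C of a WRC match or
#' the G of a GYW match; overlapping matches are counted once.  `N`
#' never matches.
#'
#' @param sequence Nucleotide string over A/C/G/T/N (or a
#'   `Biostrings::DNAString`).
#' @param gene Optional gene symbol carried in the result.
#' @param placement_space Optional integer vector of 1-based positions
#'   restricting where mutations may be placed (e.g. the panel-covered
#'   region); defaults to the whole sequence.
#' @return A list of class `motif_index`: `gene`, `sequence`, `length`,
#'   `motif_positions` (sorted, 1-based), `placement_space`,
#'   `motif_fraction` (motif positions within the space / space size).
#' @examples
#' scan_motifs("AACGTT")$motif_positions  # 3 (WRC) and 4 (GYW)
#' @export
scan_motifs <- function(sequence, gene = "", placement_space = NULL) {
  seq_chr <- toupper(as.character(sequence))
  n <- nchar(seq_chr)
  if (is.null(placement_space)) placement_space <- seq_len(max(n, 0L))
  placement_space <- sort(unique(as.integer(placement_space)))
  if (length(placement_space) &&
      (min(placement_space) < 1L || max(placement_space) > n))
    stop("placement_space outside the sequence")
  if (n < 3L) {
    return(structure(list(gene = gene, sequence = seq_chr, length = n,
                          motif_positions = integer(),
                          placement_space = placement_space,
                          motif_fraction = 0),
                     class = "motif_index"))
  }
  subj <- Biostrings::DNAString(seq_chr)
  wrc <- Biostrings::matchPattern("WRC", subj, fixed = "subject")
  gyw <- Biostrings::matchPattern("GYW", subj, fixed = "subject")
  pos <- sort(unique(c(BiocGenerics::end(wrc), BiocGenerics::start(gyw))))
  frac <- if (length(placement_space))
    length(intersect(pos, placement_space)) / length(placement_space) else 0
  structure(list(gene = gene, sequence = seq_chr, length = n,
                 motif_positions = as.integer(pos),
                 placement_space = placement_space,
                 motif_fraction = frac),
            class = "motif_index")
}

#' @export
print.motif_index <- function(x, ...) {
  cat(sprintf("WRC/GYW motif index%s: %d bp, %d motif positions (fraction %.3f over %d-position space)\n",
              if (nzchar(x$gene)) paste0(" [", x$gene, "]") else "",
              x$length, length(x$motif_positions), x$motif_fraction,
              length(x$placement_space)))
  invisible(x)
}

#' Count mutations falling in hotspot motifs
#'
#' @param positions Integer vector of 1-based mutation positions
#'   (duplicates counted per occurrence).
#' @param index A `motif_index` from [scan_motifs()].
#' @return Number of positions that are motif positions.
#' @export
count_motif_hits <- function(positions, index) {
  positions <- as.integer(positions)
  if (length(positions) &&
      (min(positions) < 1L || max(positions) > index$length))
    stop("position outside the sequence")
  sum(positions %in% index$motif_positions)
}

# positions of C or G in the index's placement space, for the mode that
# emulates C:G-restricted AID substitution placement
cg_space <- function(index) {
  chars <- strsplit(index$sequence, "")[[1]]
  intersect(index$placement_space, which(chars %in% c("C", "G")))
}

permute_hits <- function(space, is_motif_in_space, n_mut, n_perm) {
  N <- length(space)
  vapply(seq_len(n_perm),
         function(i) sum(is_motif_in_space[sample.int(N, n_mut)]),
         integer(1))
}

#' Random-placement permutation test for AID motif enrichment
#'
#' Tests whether the observed number of mutations inside WRC/GYW motifs
#' exceeds what uniform random placement would give.  Each replicate
#' places `n_mut` distinct positions uniformly over the index's
#' placement space and counts motif hits; the empirical p value is the
#' fraction of replicates with at least `observed` hits.
#'
#' @param index A `motif_index` from [scan_motifs()].
#' @param n_mut Number of mutations to place per replicate (the number
#'   observed in the gene).
#' @param observed Observed motif-hit count (`<= n_mut`).
#' @param n_perm Number of replicates. Default 100000.
#' @param seed Integer seed for reproducibility.
#' @param cg_only Restrict the placement space to C/G positions,
#'   emulating placement of C:G substitutions only. Default FALSE.
#' @param estimator `"plain"` gives `count_ge / n_perm`; `"plus_one"`
#'   gives the never-zero `(count_ge + 1) / (n_perm + 1)`.
#' @return A list of class `permutation_result`: `gene`, `n_mut`,
#'   `observed`, `n_perm`, `count_ge`, `p_empirical`, `mean_sim`,
#'   `seed`.
#' @examples
#' idx <- scan_motifs("AACGTTAACGTTAACGTT")
#' permutation_test(idx, n_mut = 4, observed = 3, n_perm = 1000, seed = 1)
#' @export
permutation_test <- function(index, n_mut, observed, n_perm = 100000L,
                             seed = NULL, cg_only = FALSE,
                             estimator = c("plain", "plus_one")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(index, "motif_index"), n_perm >= 1L)
  if (observed > n_mut) stop("observed cannot exceed n_mut")
  space <- if (cg_only) cg_space(index) else index$placement_space
  if (n_mut > length(space))
    stop("n_mut exceeds the placement space (", length(space),
         " positions)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  is_motif <- space %in% index$motif_positions
  hits <- permute_hits(space, is_motif, n_mut, n_perm)
  count_ge <- sum(hits >= observed)
  p <- if (estimator == "plain") count_ge / n_perm
       else (count_ge + 1) / (n_perm + 1)
  structure(list(gene = index$gene, n_mut = as.integer(n_mut),
                 observed = as.integer(observed),
                 n_perm = as.integer(n_perm),
                 count_ge = as.integer(count_ge), p_empirical = p,
                 mean_sim = mean(hits), seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "AID motif permutation test%s\n  observed %d/%d mutations in WRC/GYW motifs; simulated mean %.2f\n  %d/%d replicates >= observed; empirical p = %.4g\n",
    if (nzchar(x$gene)) paste0(" [", x$gene, "]") else "",
    x$observed, x$n_mut, x$mean_sim, x$count_ge, x$n_perm, x$p_empirical))
  invisible(x)
}

#' Cohort-total AID motif enrichment test
#'
#' Tests whether the total number of motif mutations across a set of
#' candidate AID-target genes exceeds random expectation: each
#' replicate places every gene's observed mutation count independently
#' and uniformly over that gene's placement space, and the per-gene
#' motif hits are summed.
#'
#' @param indexes Named list of `motif_index` objects, one per gene.
#' @param per_gene_n_mut Named integer vector (or list): mutations
#'   observed per gene; every name must have an index.
#' @param observed_total Total observed motif-hit count across genes.
#' @param n_perm Number of replicates. Default 100000.
#' @param seed Integer seed.
#' @param cg_only Restrict placement to C/G positions. Default FALSE.
#' @param estimator See [permutation_test()].
#' @return A `permutation_result` with `gene = "cohort"`.
#' @export
cohort_total_test <- function(indexes, per_gene_n_mut, observed_total,
                              n_perm = 100000L, seed = NULL,
                              cg_only = FALSE,
                              estimator = c("plain", "plus_one")) {
  estimator <- match.arg(estimator)
  per_gene_n_mut <- unlist(per_gene_n_mut)
  miss <- setdiff(names(per_gene_n_mut), names(indexes))
  if (length(miss))
    stop("no motif index for gene(s): ", paste(miss, collapse = ", "))
  if (observed_total > sum(per_gene_n_mut))
    stop("observed cannot exceed the total mutation count")
  if (!is.null(seed)) set.seed(as.integer(seed))
  totals <- integer(n_perm)
  for (g in names(per_gene_n_mut)) {
    idx <- indexes[[g]]
    space <- if (cg_only) cg_space(idx) else idx$placement_space
    n_mut <- per_gene_n_mut[[g]]
    if (n_mut > length(space))
      stop("n_mut exceeds the placement space for ", g)
    is_motif <- space %in% idx$motif_positions
    totals <- totals + permute_hits(space, is_motif, n_mut, n_perm)
  }
  count_ge <- sum(totals >= observed_total)
  p <- if (estimator == "plain") count_ge / n_perm
       else (count_ge + 1) / (n_perm + 1)
  structure(list(gene = "cohort",
                 n_mut = as.integer(sum(per_gene_n_mut)),
                 observed = as.integer(observed_total),
                 n_perm = as.integer(n_perm),
                 count_ge = as.integer(count_ge), p_empirical = p,
                 mean_sim = mean(totals), seed = seed),
            class = "permutation_result")
}

#' Read gene sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are the FASTA
#'   record ids).
#' @export
read_gene_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}
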