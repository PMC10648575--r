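#' Call EBV positivity from competitive-alignment read summaries
#'
#' A sample is EBV-positive when at least `ebv_min_reads` (2) of its
#' reads align to the EBV reference with mapping quality at least
#' `ebv_min_mapq` (60, the aligner maximum, i.e. uniquely mapped).
#'
#' @param reads Data.frame with per-read `reference_label` (one of
#'   `human`, `EBV`, `other`) and `mapq`.
#' @param sample_id Sample identifier carried in the result.
#' @param config A [pipeline_config()].
#' @return A list of class `ebv_call`: `sample_id`, `positive`,
#'   `supporting_reads`.
#' @examples
#' classify_ebv(data.frame(reference_label = c("EBV", "EBV", "human"),
#'                         mapq = c(60, 60, 60)))
#' @export
classify_ebv <- function(reads, sample_id = "sample",
                         config = pipeline_config()) {
  stopifnot(all(c("reference_label", "mapq") %in% names(reads)))
  if (any(reads$mapq < 0)) stop("mapq must be nonnegative")
  supp <- sum(reads$reference_label == "EBV" &
                reads$mapq >= config$ebv_min_mapq)
  structure(list(sample_id = sample_id,
                 positive = supp >= config$ebv_min_reads,
                 supporting_reads = as.integer(supp)),
            class = "ebv_call")
}

#' @export
print.ebv_call <- function(x, ...) {
  cat(sprintf("%s: EBV %s (%d supporting reads)\n", x$sample_id,
              if (x$positive) "positive" else "negative",
              x$supporting_reads))
  invisible(x)
}

#' Concordance of two binary sample classifications
#'
#' Cross-tabulates, e.g., EBER in situ hybridisation status against
#' competitive-alignment EBV status, keeping per-cell sample lists so
#' discordant samples can be inspected.
#'
#' @param labels_a,labels_b Named logical (or "positive"/"negative")
#'   vectors over the same sample set; names are sample ids.
#' @param name_a,name_b Axis names for the table.
#' @return A list: `table` (2x2 confusion counts) and `samples` (list of
#'   sample-id vectors per cell).
#' @export
concordance <- function(labels_a, labels_b, name_a = "a", name_b = "b") {
  as_flag <- function(x) {
    if (is.character(x)) x <- x == "positive"
    as.logical(x)
  }
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    stop("labels must be named by sample id")
  common <- intersect(names(labels_a), names(labels_b))
  if (!setequal(names(labels_a), names(labels_b)))
    stop("label vectors must cover the same sample set")
  a <- as_flag(labels_a[common]); b <- as_flag(labels_b[common])
  lv <- c("positive", "negative")
  fa <- factor(ifelse(a, "positive", "negative"), levels = lv)
  fb <- factor(ifelse(b, "positive", "negative"), levels = lv)
  tab <- table(fa, fb, dnn = c(name_a, name_b))
  cells <- list()
  for (i in lv) for (j in lv)
    cells[[paste(name_a, i, name_b, j, sep = "_")]] <-
      common[fa == i & fb == j]
  list(table = tab, samples = cells)
}

#' Two-sample t test of mutation burden between groups
#'
#' Compares per-sample mutation totals between two groups (e.g. EBV
#' positive vs negative), two-tailed.  Student's equal-variance test by
#' default; set `welch = TRUE` for the unequal-variance form.
#'
#' @param counts Numeric vector of per-sample mutation totals.
#' @param groups Binary labels (logical, or factor/character with two
#'   levels) aligned with `counts`.
#' @param welch Use Welch's correction. Default FALSE.
#' @return A list: `t` (statistic), `p` (two-sided), `df`,
#'   `group_means`.
#' @export
burden_test <- function(counts, groups, welch = FALSE) {
  stopifnot(length(counts) == length(groups))
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  if (min(table(g)) < 2L) stop("each group needs at least 2 samples")
  x <- counts[g == levels(g)[1]]
  y <- counts[g == levels(g)[2]]
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, p = 1, df = length(counts) - 2L,
                  group_means = c(mean(x), mean(y))))
    stop("zero variance in both groups with unequal means")
  }
  tt <- t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       group_means = unname(tt$estimate))
}

#' Pairwise gene co-occurrence and mutual exclusivity
#'
#' For every unordered pair of genes, a two-sided Fisher exact test on
#' the 2x2 table of samples mutated in both / one / neither, with
#' Benjamini-Hochberg adjustment across all pairs.  The direction is
#' co-occurrence when the odds ratio exceeds 1, exclusivity when below.
#'
#' @param matrix Binary gene-by-sample indicator matrix (rownames are
#'   genes, columns samples); any nonzero entry counts as mutated.
#' @return A data.frame, one row per pair: `gene_a`, `gene_b`, `both`,
#'   `a_only`, `b_only`, `neither`, `odds_ratio`, `p`, `fdr`,
#'   `direction`.
#' @export
cooccurrence <- function(matrix) {
  m <- matrix != 0
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 genes and 2 samples")
  genes <- rownames(m)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(m)))
  pairs <- utils::combn(nrow(m), 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    both <- sum(m[i, ] & m[j, ])
    a_only <- sum(m[i, ] & !m[j, ])
    b_only <- sum(!m[i, ] & m[j, ])
    neither <- sum(!m[i, ] & !m[j, ])
    ft <- fisher.test(matrix(c(both, a_only, b_only, neither), nrow = 2L))
    or <- unname(ft$estimate)
    data.frame(gene_a = genes[i], gene_b = genes[j], both = both,
               a_only = a_only, b_only = b_only, neither = neither,
               odds_ratio = or, p = ft$p.value,
               direction = if (is.na(or) || or >= 1) "co-occurrence"
                           else "exclusivity",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out[, c("gene_a", "gene_b", "both", "a_only", "b_only", "neither",
          "odds_ratio", "p", "fdr", "direction")]
}
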