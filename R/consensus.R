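#' Group tagged reads into UMI families
#'
#' Reads failing the mapping-quality or mismatch gates are excluded
#' before grouping (matching the standard error-corrected processing gates `-mmq 10 -maxNM5`:
#' mapping quality at least 10, at most 5 mismatches).  Reads without a
#' UMI are excluded with a message.  Families are keyed by
#' (UMI, chromosome, alignment start), matching amplicon chemistry where
#' the start is probe-determined.
#'
#' @param reads Tagged-read data.frame (columns `umi`, `chrom`, `start`,
#'   `bases`, `mapq`, `nm`; see [read_tagged_reads()]).
#' @param min_mapq Minimum mapping quality kept. Default 10.
#' @param max_mismatches Maximum mismatch count kept. Default 5.
#' @return A named list of family data.frames, one per
#'   `(umi, chrom, start)` key.
#' @export
group_families <- function(reads, min_mapq = 10L, max_mismatches = 5L) {
  req <- c("umi", "chrom", "start", "bases", "mapq", "nm")
  miss <- setdiff(req, names(reads))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  noumi <- is.na(reads$umi) | reads$umi == ""
  if (any(noumi))
    message(sum(noumi), " read(s) without a UMI excluded")
  keep <- !noumi & reads$mapq >= min_mapq & reads$nm <= max_mismatches
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) == 0L) return(list())
  key <- paste(reads$umi, reads$chrom, reads$start, sep = "|")
  split(reads, factor(key, levels = unique(key)))
}

# per-column unique-plurality vote over A/C/G/T; ties (or no votes) -> N
consensus_vote <- function(base_mat) {
  apply(base_mat, 2L, function(col) {
    tab <- table(factor(col[col %in% c("A", "C", "G", "T")],
                        levels = c("A", "C", "G", "T")))
    if (sum(tab) == 0L) return("N")
    top <- max(tab)
    winners <- names(tab)[tab == top]
    if (length(winners) == 1L) winners else "N"
  })
}

#' Collapse one UMI family into a consensus read
#'
#' Families with fewer than `min_family_size` member reads are removed
#' (families of fewer than 3 reads carry too little evidence) and `NULL`
#' is returned.  Otherwise each position takes the strict-majority base:
#' the unique most frequent base among A/C/G/T member calls, or `N` on a
#' tie.  Base qualities are not weighted.
#'
#' @param family One family data.frame from [group_families()]; members
#'   must share the alignment start and read length.
#' @param min_family_size Minimum members. Default 3.
#' @return A one-row data.frame (`umi`, `chrom`, `start`, `bases`,
#'   `family_size`) or `NULL` when the family is too small.
#' @export
collapse_family <- function(family, min_family_size = 3L) {
  if (nrow(family) < min_family_size) return(NULL)
  if (length(unique(family$start)) != 1L ||
      length(unique(nchar(family$bases))) != 1L)
    stop("family members must share alignment start and read length")
  mat <- do.call(rbind, strsplit(toupper(family$bases), ""))
  data.frame(umi = family$umi[1], chrom = family$chrom[1],
             start = family$start[1],
             bases = paste(consensus_vote(mat), collapse = ""),
             family_size = nrow(family), stringsAsFactors = FALSE)
}

#' Collapse all UMI families into consensus reads
#'
#' @param families List of family data.frames from [group_families()].
#' @param min_family_size Minimum members per kept family. Default 3.
#' @return A data.frame of consensus reads (zero rows when none
#'   survive).
#' @export
collapse_families <- function(families, min_family_size = 3L) {
  out <- lapply(families, collapse_family, min_family_size = min_family_size)
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(umi = character(), chrom = character(),
                      start = integer(), bases = character(),
                      family_size = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally consensus allele counts at candidate sites
#'
#' For each site, consensus reads covering the position are classified
#' as reference, alternate or other according to their base call;
#' consensus `N` calls are never counted, so they contribute to neither
#' allele nor depth.  Sites covered by no consensus read yield a
#' depth-0 row.
#'
#' @param consensus Consensus-read data.frame from
#'   [collapse_families()].
#' @param sites A [genomic_site()] data.frame (single-base ref/alt).
#' @param sample_id Sample identifier stamped on the rows.
#' @return A site count table row set (see [site_count_table()]).
#' @export
consensus_counts <- function(consensus, sites, sample_id = "sample") {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    cov <- consensus$chrom == s$chrom &
      consensus$start <= s$pos &
      consensus$start + nchar(consensus$bases) - 1L >= s$pos
    calls <- substr(consensus$bases[cov],
                    s$pos - consensus$start[cov] + 1L,
                    s$pos - consensus$start[cov] + 1L)
    data.frame(sample_id = sample_id, s,
               ref_count = sum(calls == s$ref),
               alt_count = sum(calls == s$alt),
               other_count = sum(!calls %in% c(s$ref, s$alt, "N")),
               stringsAsFactors = FALSE)
  })
  site_count_table(do.call(rbind, rows))
}
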