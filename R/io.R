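#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.x file into the package's flat variant-call table.
#' Multi-allelic records are decomposed into one row per alternate allele
#' when `decompose = TRUE`, otherwise rejected with an error.  VAF, depth
#' and alt-read support are taken from the named sample's `AF`/`AD`/`DP`
#' FORMAT fields when present, else left `NA`.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier to attach to every call (and the
#'   genotype column to read FORMAT fields from, when present).
#' @param decompose Split multi-allelic records into one call per alt
#'   allele. Default TRUE.
#' @return A variant-call data.frame ordered by (chrom, pos, alt); zero
#'   rows for a header-only VCF.
#' @export
read_variants <- function(path, sample_id, decompose = TRUE) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("failed to parse VCF '", path,
                                           "': ", conditionMessage(e)))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene = character(), consequence = character(),
                      tumor_vaf = numeric(), tumor_depth = integer(),
                      alt_reads = integer(), stringsAsFactors = FALSE))
  }
  bad <- is.na(fix$POS) | is.na(fix$REF) | is.na(fix$ALT)
  if (any(bad))
    stop("malformed VCF record at data line ", which(bad)[1], " of '",
         path, "'")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi) && !decompose)
    stop("multi-allelic record at ", fix$CHROM[which(multi)[1]], ":",
         fix$POS[which(multi)[1]],
         " -- decompose upstream or set decompose = TRUE")

  # per-sample FORMAT fields, if the sample column exists
  n <- nrow(fix)
  af <- rep(NA_character_, n); dp <- rep(NA_integer_, n)
  ad <- rep(NA_character_, n)
  if (ncol(vcf@gt) >= 2L && sample_id %in% colnames(vcf@gt)) {
    gtf <- function(el) tryCatch(
      vcfR::extract.gt(vcf, element = el, as.numeric = FALSE)[, sample_id],
      error = function(e) rep(NA_character_, n))
    af <- gtf("AF"); ad <- gtf("AD")
    dpc <- gtf("DP"); dp <- suppressWarnings(as.integer(dpc))
  }

  rows <- lapply(seq_len(n), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    afs <- if (!is.na(af[i])) strsplit(af[i], ",", fixed = TRUE)[[1]] else NULL
    # AD is ref followed by one count per alt allele
    ads <- if (!is.na(ad[i])) strsplit(ad[i], ",", fixed = TRUE)[[1]] else NULL
    out <- data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                      ref = fix$REF[i], alt = alts,
                      stringsAsFactors = FALSE)
    out$tumor_vaf <- NA_real_
    out$alt_reads <- NA_integer_
    out$tumor_depth <- dp[i]
    for (k in seq_along(alts)) {
      if (!is.null(afs) && length(afs) >= k)
        out$tumor_vaf[k] <- suppressWarnings(as.numeric(afs[k]))
      if (!is.null(ads) && length(ads) >= k + 1L) {
        out$alt_reads[k] <- suppressWarnings(as.integer(ads[k + 1L]))
        if (is.na(dp[i]))
          out$tumor_depth[k] <- sum(suppressWarnings(as.integer(ads)),
                                    na.rm = TRUE)
      }
    }
    if (any(is.na(out$tumor_vaf) & !is.na(out$alt_reads) &
            !is.na(out$tumor_depth) & out$tumor_depth > 0)) {
      idx <- is.na(out$tumor_vaf) & !is.na(out$alt_reads) &
        !is.na(out$tumor_depth) & out$tumor_depth > 0
      out$tumor_vaf[idx] <- out$alt_reads[idx] / out$tumor_depth[idx]
    }
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
  variant_calls(genomic_site(out$chrom, out$pos, out$ref, out$alt),
                sample_id = sample_id,
                tumor_vaf = out$tumor_vaf, tumor_depth = out$tumor_depth,
                alt_reads = out$alt_reads)
}

#' Build target regions from interval coordinates
#'
#' Intervals are half-open, 0-based `[start, end)` as in BED.  Overlapping
#' or adjacent intervals are merged and the result sorted, so the stored
#' regions are always disjoint.
#'
#' @param chrom Chromosome names.
#' @param start 0-based interval starts.
#' @param end Interval ends (exclusive); must exceed `start`.
#' @param label Panel name. Default "targets".
#' @return A `GRanges` of merged 1-based intervals with a `label`
#'   metadata field.
#' @export
target_regions <- function(chrom, start, end, label = "targets") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop("interval starts must be < ends")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read target regions from a BED file
#'
#' @param path BED file (first three columns chrom, start, end; 0-based
#'   half-open).
#' @param label Panel name attached to the regions.
#' @return A merged, sorted `GRanges` (see [target_regions()]).
#' @export
read_target_bed <- function(path, label = basename(path)) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(bed) < 3L) stop("BED file must have at least 3 columns")
  target_regions(bed[[1]], bed[[2]], bed[[3]], label = label)
}

#' Keep variants falling inside target regions
#'
#' A variant at 1-based position p is kept when some region covers p
#' (i.e. its 0-based half-open interval `[start, end)` satisfies
#' `start < p <= end`).  Input order is preserved.  Variants on
#' chromosomes absent from the regions are dropped with a warning, so
#' partial panels still run.
#'
#' @param variants A variant-call data.frame.
#' @param regions A `GRanges` from [target_regions()] /
#'   [read_target_bed()].
#' @return The subset of `variants` inside the regions.
#' @export
intersect_targets <- function(variants, regions) {
  if (nrow(variants) == 0L || length(regions) == 0L)
    return(variants[0, , drop = FALSE])
  unknown <- !(variants$chrom %in%
                 unique(as.character(GenomicRanges::seqnames(regions))))
  if (any(unknown))
    warning(sum(unknown), " variant(s) on chromosomes absent from '",
            S4Vectors::metadata(regions)$label, "' dropped")
  v <- variants[!unknown, , drop = FALSE]
  if (nrow(v) == 0L) return(v)
  q <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  hit <- IRanges::overlapsAny(q, regions)
  v[hit, , drop = FALSE]
}

#' Write stage results to TSV
#'
#' @param results A data.frame of flat records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  stopifnot(is.data.frame(results))
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a TSV report written by [write_report()]
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read UMI-tagged reads from TSV
#'
#' Fixture-friendly flat representation of tagged reads: one row per
#' read with its UMI, alignment start, base string (aligned, starting at
#' `start`), mapping quality and mismatch count.
#'
#' @param path TSV with columns `umi`, `chrom`, `start`, `bases`, `mapq`,
#'   `nm`.
#' @return A data.frame of tagged reads.
#' @export
read_tagged_reads <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", umi = "character"))
  req <- c("umi", "chrom", "start", "bases", "mapq", "nm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$start <- as.integer(df$start)
  df$mapq <- as.integer(df$mapq)
  df$nm <- as.integer(df$nm)
  df
}

#' Read UMI-tagged reads from SAM/BAM
#'
#' The UMI is taken from the `RX` tag, or failing that from a
#' `...:UMI` suffix on the read name; the mismatch count from the `NM`
#' tag.  Soft-clip-free alignments are assumed (amplicon chemistry); the
#' base string is the read sequence anchored at the alignment start.
#'
#' @param path SAM or BAM file.
#' @return A data.frame in the layout of [read_tagged_reads()].
#' @export
read_tagged_sam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  bf <- Rsamtools::BamFile(path)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq", "mapq"),
    tag = c("RX", "NM"))
  b <- Rsamtools::scanBam(bf, param = p)[[1]]
  umi <- b$tag$RX
  if (is.null(umi)) umi <- rep(NA_character_, length(b$qname))
  noumi <- is.na(umi)
  if (any(noumi)) {
    # fall back to read-name suffix after the last ':'
    umi[noumi] <- sub("^.*:", "", b$qname[noumi])
    umi[umi == b$qname] <- NA_character_
  }
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(0L, length(b$qname))
  nm[is.na(nm)] <- 0L
  data.frame(umi = umi, chrom = as.character(b$rname), start = b$pos,
             bases = as.character(b$seq), mapq = b$mapq, nm = as.integer(nm),
             stringsAsFactors = FALSE)
}
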