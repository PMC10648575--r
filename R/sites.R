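#' Construct a table of genomic sites
#'
#' A site is a candidate substitution or indel: chromosome, 1-based
#' position, reference and alternate allele (indels anchored, VCF style).
#' All arguments are recycled to a common length.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions (integer, >= 1).
#' @param ref Reference allele strings over A/C/G/T.
#' @param alt Alternate allele strings over A/C/G/T; must differ from
#'   `ref` row-wise.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' genomic_site("chr1", 100, "A", "T")
#' @export
genomic_site <- function(chrom, pos, ref, alt) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   stringsAsFactors = FALSE)
  if (any(df$pos < 1L)) stop("positions must be >= 1 (1-based)")
  if (any(!grepl("^[ACGT]+$", df$ref)) || any(!grepl("^[ACGT]+$", df$alt)))
    stop("alleles must be non-empty strings over {A,C,G,T}")
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  df
}

# canonical key used for joins and set operations
site_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

pair_key <- function(df) {
  paste(df$sample_id, site_key(df), sep = "@")
}

#' Construct or validate a table of variant calls
#'
#' A variant call attaches a sample, optional gene/consequence annotation
#' and tumor read support to a genomic site.
#'
#' @param site A data.frame from [genomic_site()] (or columns `chrom`,
#'   `pos`, `ref`, `alt`).
#' @param sample_id Sample identifiers.
#' @param gene Gene symbols ("" when unknown).
#' @param consequence Controlled consequence terms ("" when unknown).
#' @param tumor_vaf Variant allele fraction in [0, 1] (NA allowed).
#' @param tumor_depth Total reads at the site (NA allowed).
#' @param alt_reads Variant-supporting reads (NA allowed).
#' @return A data.frame of variant calls, one row per (sample, site, alt).
#' @export
variant_calls <- function(site, sample_id, gene = "", consequence = "",
                          tumor_vaf = NA_real_, tumor_depth = NA_integer_,
                          alt_reads = NA_integer_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   site[, c("chrom", "pos", "ref", "alt")],
                   gene = as.character(gene),
                   consequence = as.character(consequence),
                   tumor_vaf = as.numeric(tumor_vaf),
                   tumor_depth = as.integer(tumor_depth),
                   alt_reads = as.integer(alt_reads),
                   stringsAsFactors = FALSE)
  ok <- is.na(df$tumor_vaf) | (df$tumor_vaf >= 0 & df$tumor_vaf <= 1)
  if (!all(ok)) stop("tumor_vaf must lie in [0, 1]")
  both <- !is.na(df$alt_reads) & !is.na(df$tumor_depth)
  if (any(df$alt_reads[both] > df$tumor_depth[both]))
    stop("alt_reads cannot exceed tumor_depth")
  # VAF must agree with alt/depth within rounding where all three known
  chk <- both & !is.na(df$tumor_vaf) & df$tumor_depth > 0
  if (any(abs(df$tumor_vaf[chk] - df$alt_reads[chk] / df$tumor_depth[chk]) >
          0.5 / pmax(df$tumor_depth[chk], 1) + 1e-6))
    stop("tumor_vaf inconsistent with alt_reads / tumor_depth")
  df
}

#' Construct or validate a site count table
#'
#' The substrate of the background Fisher test: error-corrected reference,
#' alternate and other-allele consensus read counts per (sample, site).
#'
#' @param df A data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `ref_count`, `alt_count` and optionally `other_count`
#'   (defaults to 0).
#' @return The validated data.frame with an added `depth` column
#'   (`ref_count + alt_count + other_count`).
#' @export
site_count_table <- function(df) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(df$other_count)) df$other_count <- 0L
  df$pos <- as.integer(df$pos)
  for (cc in c("ref_count", "alt_count", "other_count")) {
    df[[cc]] <- as.integer(df[[cc]])
    if (any(is.na(df[[cc]])) || any(df[[cc]] < 0L))
      stop(cc, " must be nonnegative")
  }
  if (anyDuplicated(pair_key(df)))
    stop("duplicate (sample, site) keys in count table")
  df$depth <- df$ref_count + df$alt_count + df$other_count
  df
}

#' Read a site count table from TSV
#'
#' @param path TSV with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count` and optionally `other_count`.
#' @return A validated count table (see [site_count_table()]).
#' @export
read_count_table <- function(path) {
  site_count_table(read.delim(path, stringsAsFactors = FALSE,
                              colClasses = c(chrom = "character")))
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `patient_id`, `tissue`
#'   (tumor/normal) and optionally `ebv_eber`
#'   (positive/negative/unknown), `relapse`, `mutation_count`.
#' @return A data.frame; tumor and normal of one patient share
#'   `patient_id`.
#' @export
read_sample_meta <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "tissue")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(meta$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if (!is.null(meta$mutation_count)) {
    known <- !is.na(meta$mutation_count)
    if (any(meta$mutation_count[known] < 0))
      stop("mutation_count must be nonnegative when known")
  }
  meta
}
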