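filter_decision <- function(status, failed_rules = character()) {
  structure(list(status = status, failed_rules = failed_rules),
            class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat(x$status)
  if (length(x$failed_rules))
    cat(" [", paste(x$failed_rules, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Validate an indel from consensus-read counts
#'
#' Applies the consensus-bam indel rules.  With an evaluable normal
#' (depth above the bound), the paired path requires: tumor and normal
#' depth > 5 consensus reads, > 1 tumor-supporting read, < 20
#' normal-supporting reads, tumor VAF > 0.01% and normal VAF < 5%
#' (inequalities strict as stated; the depth strictness is switchable in
#' [indel_rules()]).  Otherwise the tumor-only path requires 5 tumor
#' consensus reads, at least 1 supporting read and tumor VAF > 0.01%,
#' yielding `TUMOR_ONLY`.
#'
#' @param tumor_depth,tumor_alt Tumor consensus depth and supporting
#'   reads.
#' @param normal_depth,normal_alt Normal consensus depth and supporting
#'   reads (NA when the normal could not be assessed).
#' @param tumor_vaf,normal_vaf Consensus VAFs; computed from the counts
#'   when NA and depth > 0.
#' @param config A [pipeline_config()] (uses its `indel` rules).
#' @return A `filter_decision`: status PASS / TUMOR_ONLY / FAIL /
#'   NOT_EVALUABLE with the identifiers of every failed rule.
#' @examples
#' validate_indel(10, 2, 10, 0)            # PASS
#' validate_indel(10, 1, normal_depth = 3) # TUMOR_ONLY
#' @export
validate_indel <- function(tumor_depth, tumor_alt,
                           normal_depth = NA_real_, normal_alt = NA_real_,
                           tumor_vaf = NA_real_, normal_vaf = NA_real_,
                           config = pipeline_config()) {
  r <- config$indel
  if (is.na(tumor_depth)) return(filter_decision("NOT_EVALUABLE"))
  if (is.na(tumor_vaf) && tumor_depth > 0) tumor_vaf <- tumor_alt / tumor_depth
  if (is.na(normal_vaf) && !is.na(normal_depth) && normal_depth > 0)
    normal_vaf <- normal_alt / normal_depth
  ndepth_ok <- !is.na(normal_depth) &&
    (if (r$paired_depth_strict) normal_depth > r$min_depth
     else normal_depth >= r$min_depth)
  if (ndepth_ok) {
    failed <- character()
    tdepth_ok <- if (r$paired_depth_strict) tumor_depth > r$min_depth
                 else tumor_depth >= r$min_depth
    if (!tdepth_ok) failed <- c(failed, "indel.min_depth.tumor")
    if (!(tumor_alt >= r$min_tumor_alt))
      failed <- c(failed, "indel.min_tumor_alt")
    if (!(normal_alt < r$max_normal_alt))
      failed <- c(failed, "indel.max_normal_alt")
    if (!(tumor_vaf > r$min_tumor_vaf))
      failed <- c(failed, "indel.min_tumor_vaf")
    if (!(normal_vaf < r$max_normal_vaf))
      failed <- c(failed, "indel.max_normal_vaf")
    return(filter_decision(if (length(failed)) "FAIL" else "PASS", failed))
  }
  # tumor-only path
  failed <- character()
  tdepth_ok <- if (r$tumor_only_depth_strict) tumor_depth > r$min_depth
               else tumor_depth >= r$min_depth
  if (!tdepth_ok) failed <- c(failed, "indel.min_depth.tumor_only")
  if (!(tumor_alt >= r$tumor_only_min_alt))
    failed <- c(failed, "indel.tumor_only_min_alt")
  if (!(tumor_vaf > r$min_tumor_vaf))
    failed <- c(failed, "indel.min_tumor_vaf")
  filter_decision(if (length(failed)) "FAIL" else "TUMOR_ONLY", failed)
}

#' Filter a de novo variant call on consensus statistics
#'
#' A candidate passes when tumor and normal consensus depth are each at
#' least 5 reads, the normal VAF is below 5%, the tumor VAF above 0.5%,
#' the normal carries fewer than 5 supporting consensus reads and the
#' tumor at least 2.
#'
#' @param tumor_depth,tumor_alt,tumor_vaf Tumor consensus statistics.
#' @param normal_depth,normal_alt,normal_vaf Normal consensus
#'   statistics.
#' @param config A [pipeline_config()] (uses its `denovo` rules).
#' @return A `filter_decision` (PASS or FAIL with failed rule ids;
#'   NOT_EVALUABLE when a required quantity is missing).
#' @examples
#' filter_denovo(200, 3, 0.015, 150, 0, 0)  # PASS
#' @export
filter_denovo <- function(tumor_depth, tumor_alt, tumor_vaf,
                          normal_depth, normal_alt, normal_vaf,
                          config = pipeline_config()) {
  if (anyNA(c(tumor_depth, tumor_alt, tumor_vaf,
              normal_depth, normal_alt, normal_vaf)))
    return(filter_decision("NOT_EVALUABLE"))
  r <- config$denovo
  failed <- character()
  if (!(tumor_depth >= r$min_depth)) failed <- c(failed, "denovo.min_depth.tumor")
  if (!(normal_depth >= r$min_depth)) failed <- c(failed, "denovo.min_depth.normal")
  if (!(normal_vaf < r$max_normal_vaf)) failed <- c(failed, "denovo.max_normal_vaf")
  if (!(tumor_vaf > r$min_tumor_vaf)) failed <- c(failed, "denovo.min_tumor_vaf")
  if (!(normal_alt <= r$max_normal_alt)) failed <- c(failed, "denovo.max_normal_alt")
  if (!(tumor_alt >= r$min_tumor_alt)) failed <- c(failed, "denovo.min_tumor_alt")
  filter_decision(if (length(failed)) "FAIL" else "PASS", failed)
}

#' Consequence classes kept by default
#'
#' The protein-altering classes retained when restricting to
#' non-synonymous coding mutations.
#' @export
protein_altering_consequences <- c(
  "missense", "missense_variant",
  "nonsense", "stop_gained", "stop_gain", "stop_lost",
  "frameshift", "frameshift_variant",
  "inframe_insertion", "inframe_deletion", "inframe_indel",
  "splice_donor", "splice_donor_variant",
  "splice_acceptor", "splice_acceptor_variant",
  "start_lost", "start_loss")

#' Keep protein-altering variants by consequence
#'
#' @param variants Variant-call data.frame with a populated
#'   `consequence` column.
#' @param keep_classes Character vector of consequence terms to keep.
#'   Defaults to [protein_altering_consequences].
#' @param known_classes Terms recognised as valid annotations; variants
#'   with a term outside this union are dropped with a warning.
#' @return The filtered data.frame, input order preserved.
#' @export
filter_consequence <- function(variants,
                               keep_classes = protein_altering_consequences,
                               known_classes = c(keep_classes,
                                                 "synonymous",
                                                 "synonymous_variant",
                                                 "intergenic",
                                                 "intergenic_variant",
                                                 "intron_variant",
                                                 "5_prime_UTR_variant",
                                                 "3_prime_UTR_variant")) {
  cons <- tolower(variants$consequence)
  unknown <- !(cons %in% tolower(known_classes))
  if (any(unknown))
    warning(sum(unknown), " variant(s) with unrecognised consequence ",
            "term dropped: ",
            paste(unique(variants$consequence[unknown]), collapse = ", "))
  variants[cons %in% tolower(keep_classes), , drop = FALSE]
}

#' Remove variants already discovered elsewhere
#'
#' Drops variants whose (sample, chrom, pos, ref, alt) key appears in
#' `known` (e.g. the exome-discovered set, so de novo discovery reports
#' only new sites).  Both lists are assumed normalised (left-aligned,
#' decomposed).
#'
#' @param variants Variant-call data.frame.
#' @param known Data.frame of already-known variants with the same key
#'   columns.
#' @return `variants` without the known rows, order preserved.
#' @export
remove_known <- function(variants, known) {
  if (is.null(known) || nrow(known) == 0L) return(variants)
  variants[!(pair_key(variants) %in% pair_key(known)), , drop = FALSE]
}

#' Rescue allowlisted variants
#'
#' Variants whose key appears on an explicit allowlist (e.g. sites
#' rescued after manual review) are re-added to a filtered set
#' regardless of their filter decision.
#'
#' @param filtered Variant-call data.frame after filtering.
#' @param variants The unfiltered variants.
#' @param allowlist Data.frame of (sample_id, chrom, pos, ref, alt) keys
#'   to force-keep.
#' @return `filtered` plus any allowlisted rows of `variants` not
#'   already present.
#' @export
apply_allowlist <- function(filtered, variants, allowlist) {
  if (is.null(allowlist) || nrow(allowlist) == 0L) return(filtered)
  want <- variants[pair_key(variants) %in% pair_key(allowlist), ,
                   drop = FALSE]
  add <- want[!(pair_key(want) %in% pair_key(filtered)), , drop = FALSE]
  rbind(filtered, add)
}
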