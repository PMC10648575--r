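#' Indel validation rule thresholds
#'
#' Thresholds for consensus-read indel validation.  The paired path
#' requires, in the tumor and the normal, a consensus depth above
#' `min_depth`, more than `min_tumor_alt - 1` tumor-supporting consensus
#' reads, fewer than `max_normal_alt` normal-supporting reads, a tumor VAF
#' above `min_tumor_vaf` (0.01%) and a normal VAF below `max_normal_vaf`
#' (5%).  When the normal lacks evaluable depth the tumor-only path
#' requires `min_depth` tumor consensus reads, at least
#' `tumor_only_min_alt` supporting reads and the same tumor VAF bound.
#'
#' The protocol states the paired depth bound as strict
#' (`> 5`) but the tumor-only bound as a bare count (`5 consensus reads`,
#' read as `>= 5`); both readings are switchable via
#' `paired_depth_strict` and `tumor_only_depth_strict`.
#'
#' @param min_depth Minimum consensus depth (reads). Default 5.
#' @param min_tumor_alt Minimum tumor-supporting consensus reads on the
#'   paired path (strictly more than 1 read, i.e. at least 2). Default 2.
#' @param max_normal_alt Normal-supporting reads must be strictly below
#'   this. Default 20.
#' @param min_tumor_vaf Tumor VAF must be strictly above this fraction.
#'   Default 1e-4 (0.01%).
#' @param max_normal_vaf Normal VAF must be strictly below this fraction.
#'   Default 0.05 (5%).
#' @param tumor_only_min_alt Minimum tumor-supporting reads on the
#'   tumor-only path. Default 1.
#' @param paired_depth_strict Read the paired depth bound as `> min_depth`
#'   (TRUE, the default reading) or `>= min_depth`. Default TRUE.
#' @param tumor_only_depth_strict Read the tumor-only depth bound as
#'   `> min_depth` or `>= min_depth` (FALSE, the default reading). Default FALSE.
#' @return A named list of class `indel_rules`.
#' @export
indel_rules <- function(min_depth = 5L,
                        min_tumor_alt = 2L,
                        max_normal_alt = 20L,
                        min_tumor_vaf = 1e-4,
                        max_normal_vaf = 0.05,
                        tumor_only_min_alt = 1L,
                        paired_depth_strict = TRUE,
                        tumor_only_depth_strict = FALSE) {
  structure(list(
    min_depth = as.integer(min_depth),
    min_tumor_alt = as.integer(min_tumor_alt),
    max_normal_alt = as.integer(max_normal_alt),
    min_tumor_vaf = min_tumor_vaf,
    max_normal_vaf = max_normal_vaf,
    tumor_only_min_alt = as.integer(tumor_only_min_alt),
    paired_depth_strict = isTRUE(paired_depth_strict),
    tumor_only_depth_strict = isTRUE(tumor_only_depth_strict)
  ), class = "indel_rules")
}

#' De novo variant filter thresholds
#'
#' A de novo candidate passes when both tumor and normal consensus depth
#' are at least `min_depth`, the normal VAF is below `max_normal_vaf`, the
#' tumor VAF is above `min_tumor_vaf`, the normal has at most
#' `max_normal_alt` supporting consensus reads (strictly fewer than 5) and
#' the tumor has at least `min_tumor_alt`.
#'
#' @param min_depth Minimum consensus depth in tumor and normal. Default 5.
#' @param max_normal_vaf Normal VAF strictly below. Default 0.05.
#' @param min_tumor_vaf Tumor VAF strictly above. Default 0.005.
#' @param max_normal_alt Maximum normal-supporting reads (i.e. < 5).
#'   Default 4.
#' @param min_tumor_alt Minimum tumor-supporting reads. Default 2.
#' @return A named list of class `denovo_rules`.
#' @export
denovo_rules <- function(min_depth = 5L,
                         max_normal_vaf = 0.05,
                         min_tumor_vaf = 0.005,
                         max_normal_alt = 4L,
                         min_tumor_alt = 2L) {
  structure(list(
    min_depth = as.integer(min_depth),
    max_normal_vaf = max_normal_vaf,
    min_tumor_vaf = min_tumor_vaf,
    max_normal_alt = as.integer(max_normal_alt),
    min_tumor_alt = as.integer(min_tumor_alt)
  ), class = "denovo_rules")
}

#' Pipeline configuration
#'
#' Every numeric threshold used across the pipeline, in one auditable
#' place.  Defaults encode the validation protocol: a 100-read
#' error-corrected depth gate for SNV validation, retention of sites with
#' Holm-adjusted p below 0.1 during background iteration and a final
#' carry-forward threshold of 0.05, a matched-normal significance bound of
#' 0.05, UMI read families of at least 3 reads with mapping quality >= 10
#' and at most 5 mismatches, EBV positivity at >= 2 reads with mapping
#' quality >= 60, and 100,000 permutation replicates for motif enrichment.
#'
#' @param min_validation_depth Minimum error-corrected depth (tumor, and
#'   normal where evaluable) for SNV validation. Default 100.
#' @param retain_alpha Holm-adjusted p threshold (strictly below) for
#'   retaining a site during background iteration. Default 0.1.
#' @param final_alpha Adjusted p threshold (at or below) for carrying a
#'   retained site forward as validated. Default 0.05.
#' @param normal_alpha Matched normal must have adjusted p strictly above
#'   this for a full PASS. Default 0.05.
#' @param min_family_size Minimum reads per UMI family kept for consensus.
#'   Default 3.
#' @param min_mapq Minimum read mapping quality before family grouping.
#'   Default 10.
#' @param max_mismatches Maximum per-read mismatch count (NM) before
#'   family grouping. Default 5.
#' @param indel An [indel_rules()] object.
#' @param denovo A [denovo_rules()] object.
#' @param ebv_min_reads Minimum qualifying EBV reads for positivity.
#'   Default 2.
#' @param ebv_min_mapq Minimum mapping quality of a qualifying EBV read.
#'   Default 60.
#' @param n_permutations Permutation replicates for motif enrichment.
#'   Default 100000.
#' @param exclude_matched_normal Exclude the matched normal from the
#'   background pool of its tumor's Fisher test. Default FALSE (the pool
#'   is all other samples).
#' @param rng_seed Optional integer seed recorded with the configuration.
#' @return A named list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config()
#' cfg$retain_alpha
#' @export
pipeline_config <- function(min_validation_depth = 100L,
                            retain_alpha = 0.1,
                            final_alpha = 0.05,
                            normal_alpha = 0.05,
                            min_family_size = 3L,
                            min_mapq = 10L,
                            max_mismatches = 5L,
                            indel = indel_rules(),
                            denovo = denovo_rules(),
                            ebv_min_reads = 2L,
                            ebv_min_mapq = 60L,
                            n_permutations = 100000L,
                            exclude_matched_normal = FALSE,
                            rng_seed = NULL) {
  cfg <- structure(list(
    min_validation_depth = as.integer(min_validation_depth),
    retain_alpha = retain_alpha,
    final_alpha = final_alpha,
    normal_alpha = normal_alpha,
    min_family_size = as.integer(min_family_size),
    min_mapq = as.integer(min_mapq),
    max_mismatches = as.integer(max_mismatches),
    indel = indel,
    denovo = denovo,
    ebv_min_reads = as.integer(ebv_min_reads),
    ebv_min_mapq = as.integer(ebv_min_mapq),
    n_permutations = as.integer(n_permutations),
    exclude_matched_normal = isTRUE(exclude_matched_normal),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  ), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks that all thresholds are nonnegative and all significance levels
#' lie strictly in (0, 1).  Called by [pipeline_config()]; exported so
#' configurations deserialised from YAML can be re-checked.
#'
#' @param cfg A `pipeline_config` object.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  alphas <- c(retain_alpha = cfg$retain_alpha, final_alpha = cfg$final_alpha,
              normal_alpha = cfg$normal_alpha)
  bad <- alphas <= 0 | alphas >= 1
  if (any(bad))
    stop("significance levels must lie in (0, 1): ",
         paste(names(alphas)[bad], collapse = ", "))
  counts <- c(cfg$min_validation_depth, cfg$min_family_size, cfg$min_mapq,
              cfg$max_mismatches, cfg$ebv_min_reads, cfg$ebv_min_mapq,
              cfg$n_permutations,
              unlist(cfg$indel[c("min_depth", "min_tumor_alt",
                                 "max_normal_alt", "tumor_only_min_alt")]),
              unlist(cfg$denovo[c("min_depth", "max_normal_alt",
                                  "min_tumor_alt")]))
  if (any(counts < 0)) stop("count thresholds must be nonnegative")
  fracs <- c(cfg$indel$min_tumor_vaf, cfg$indel$max_normal_vaf,
             cfg$denovo$min_tumor_vaf, cfg$denovo$max_normal_vaf)
  if (any(fracs < 0 | fracs > 1)) stop("VAF thresholds must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  SNV validation: depth >= %d, retain p < %g, final p <= %g, normal p > %g\n",
              x$min_validation_depth, x$retain_alpha, x$final_alpha,
              x$normal_alpha))
  cat(sprintf("  UMI consensus:  family >= %d reads, MAPQ >= %d, NM <= %d\n",
              x$min_family_size, x$min_mapq, x$max_mismatches))
  cat(sprintf("  EBV positivity: >= %d reads at MAPQ >= %d\n",
              x$ebv_min_reads, x$ebv_min_mapq))
  cat(sprintf("  Motif test:     %d permutations\n", x$n_permutations))
  invisible(x)
}

#' Write a configuration to YAML
#'
#' @param cfg A `pipeline_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
config_to_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  lst <- unclass(cfg)
  lst$indel <- unclass(lst$indel)
  lst$denovo <- unclass(lst$denovo)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Fields absent from the file fall back to the package defaults; fields
#' map 1:1 onto [pipeline_config()] arguments.
#'
#' @param path YAML file written by [config_to_yaml()] or by hand.
#' @return A validated `pipeline_config`.
#' @export
config_from_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  args <- lst[setdiff(names(lst), c("indel", "denovo"))]
  if (!is.null(lst$indel)) args$indel <- do.call(indel_rules, lst$indel)
  if (!is.null(lst$denovo)) args$denovo <- do.call(denovo_rules, lst$denovo)
  do.call(pipeline_config, args)
}
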