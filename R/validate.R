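#' One-sided exact p for variant enrichment over background
#'
#' Upper tail of the hypergeometric distribution for the 2x2 table
#' `[[alt_fg, ref_fg], [alt_bg, ref_bg]]`: the probability, with the
#' margins fixed, of the foreground sample carrying at least its observed
#' number of variant-supporting reads.  Identical to
#' `fisher.test(alternative = "greater")` but vectorised.
#'
#' @param alt_fg,ref_fg Foreground alt/ref consensus counts.
#' @param alt_bg,ref_bg Pooled background alt/ref counts.
#' @return Numeric vector of one-sided p values.
#' @export
fisher_alt_p <- function(alt_fg, ref_fg, alt_bg, ref_bg) {
  phyper(alt_fg - 1, alt_fg + alt_bg, ref_fg + ref_bg, alt_fg + ref_fg,
         lower.tail = FALSE)
}

#' Fisher exact test of one (sample, site) pair against pooled background
#'
#' Compares the sample's reference and variant read counts at a site
#' with the summed reference and variant counts at that site across all
#' other samples (the empirical sequencing-error background), one-sided
#' toward variant enrichment.  (sample, site) pairs in `excluded` --
#' typically variants retained in earlier validation rounds -- are
#' omitted from the background pool.
#'
#' @param counts A site count table (see [site_count_table()]).
#' @param sample_id Foreground sample.
#' @param site One-row [genomic_site()] data.frame.
#' @param excluded Optional data.frame of (sample_id, chrom, pos, ref,
#'   alt) pairs to omit from the background.
#' @return A list of class `fisher_record`: `sample_id`, `site`, `table`
#'   (2x2 counts), `p_raw`, `p_adj` (NA for a single test), `iteration`.
#' @examples
#' tab <- site_count_table(data.frame(
#'   sample_id = c("s1", "s2", "s3"), chrom = "chr1", pos = 100,
#'   ref = "A", alt = "T", ref_count = c(95, 2000, 1990),
#'   alt_count = c(5, 1, 1)))
#' fisher_site_test(tab, "s1", genomic_site("chr1", 100, "A", "T"))
#' @export
fisher_site_test <- function(counts, sample_id, site, excluded = NULL) {
  skey <- site_key(site)
  at_site <- counts[site_key(counts) == skey, , drop = FALSE]
  fg <- at_site[at_site$sample_id == sample_id, , drop = FALSE]
  if (nrow(fg) != 1L)
    stop("no counts for sample ", sample_id, " at ", skey)
  bg <- at_site[at_site$sample_id != sample_id, , drop = FALSE]
  if (!is.null(excluded) && nrow(bg))
    bg <- bg[!(pair_key(bg) %in% pair_key(excluded)), , drop = FALSE]
  if (nrow(bg) == 0L)
    stop("empty background pool at ", skey)
  tab <- matrix(c(fg$alt_count, fg$ref_count,
                  sum(bg$alt_count), sum(bg$ref_count)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("foreground", "background"),
                                c("alt", "ref")))
  structure(list(sample_id = sample_id, site = site, table = tab,
                 p_raw = fisher_alt_p(tab[1, 1], tab[1, 2],
                                      tab[2, 1], tab[2, 2]),
                 p_adj = NA_real_, iteration = 1L),
            class = "fisher_record")
}

#' @export
print.fisher_record <- function(x, ...) {
  cat(sprintf("Fisher background test: %s @ %s\n", x$sample_id,
              site_key(x$site)))
  print(x$table)
  cat(sprintf("  one-sided p = %.4g\n", x$p_raw))
  invisible(x)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sorts p values ascending, takes the running maximum of
#' `(m - i + 1) * p_(i)` capped at 1, and maps back to input order.
#' Adjusted values never fall below the raw ones.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values in input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Iterative background-noise validation
#'
#' The pipeline's core procedure.  In each round, every not-yet-retained
#' candidate (sample, site) pair is Fisher-tested against the pooled
#' background of all other samples at its site, omitting every pair
#' retained in earlier rounds; the round's p values are Holm-adjusted as
#' one family and pairs with adjusted p strictly below `retain_alpha`
#' are retained.  Rounds repeat until one retains nothing, so true
#' variants are progressively removed from the noise estimate.  Retained
#' pairs whose adjusted p (from their retention round) is at or below
#' `final_alpha` are carried forward as validated.
#'
#' A site whose background pool empties mid-iteration (every other
#' sample's pair already retained) scores p = 1 for the remaining
#' candidates there; sites assayed in fewer than two samples are an
#' error up front.
#'
#' @param counts A site count table covering all samples.
#' @param candidates Data.frame of candidate pairs (`sample_id`,
#'   `chrom`, `pos`, `ref`, `alt`); must all be present in `counts`.
#' @param retain_alpha Retention threshold (adjusted p strictly below).
#'   Default 0.1.
#' @param final_alpha Carry-forward threshold (adjusted p at or below).
#'   Default 0.05.
#' @param matched Optional character vector, one per candidate row: a
#'   sample whose counts are additionally excluded from that candidate's
#'   background (used to keep a matched normal out of its tumor's pool);
#'   NA for none.
#' @return A list: `retained` (candidate rows with `p_raw`, `p_adj`,
#'   `iteration` of retention and `carried_forward`), `results` (every
#'   candidate with its definitive statistics), and `log` (every test of
#'   every round).
#' @export
iterate_validation <- function(counts, candidates, retain_alpha = 0.1,
                               final_alpha = 0.05, matched = NULL) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L)
  ckey <- pair_key(candidates)
  if (anyDuplicated(ckey)) stop("duplicate candidate pairs")
  rkey <- pair_key(counts)
  cidx <- match(ckey, rkey)
  if (anyNA(cidx))
    stop("candidate(s) missing from count table: ",
         paste(head(ckey[is.na(cidx)], 3L), collapse = ", "))
  if (length(unique(counts$sample_id)) < 2L)
    stop("background pooling needs at least 2 samples")
  csite <- site_key(counts)
  cand_site <- csite[cidx]
  nsamp_site <- table(csite)
  solo <- nsamp_site[unique(cand_site)] < 2L
  if (any(solo))
    stop("site assayed in fewer than 2 samples: ",
         names(solo)[which(solo)[1]])
  if (!is.null(matched)) {
    stopifnot(length(matched) == nrow(candidates))
    midx <- match(ifelse(is.na(matched), NA_character_,
                         paste(matched, cand_site, sep = "@")), rkey)
  } else midx <- rep(NA_integer_, nrow(candidates))

  n_cand <- nrow(candidates)
  retained <- logical(n_cand)
  ret_iter <- rep(NA_integer_, n_cand)
  def_p_raw <- rep(NA_real_, n_cand)
  def_p_adj <- rep(NA_real_, n_cand)
  logs <- list()
  max_iter <- n_cand + 1L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("iteration cap exceeded; this should be impossible")
    active <- which(!retained)
    if (!length(active)) break
    # background totals per site over rows not excluded as retained
    excl_rows <- cidx[retained]
    inc <- rep(TRUE, nrow(counts))
    inc[excl_rows] <- FALSE
    tot_alt <- rowsum(counts$alt_count * inc, csite)
    tot_ref <- rowsum(counts$ref_count * inc, csite)
    sidx <- match(cand_site[active], rownames(tot_alt))
    own_alt <- counts$alt_count[cidx[active]]
    own_ref <- counts$ref_count[cidx[active]]
    bg_alt <- tot_alt[sidx] - own_alt
    bg_ref <- tot_ref[sidx] - own_ref
    m_act <- midx[active]
    has_m <- !is.na(m_act) & inc[ifelse(is.na(m_act), 1L, m_act)]
    if (any(has_m)) {
      bg_alt[has_m] <- bg_alt[has_m] - counts$alt_count[m_act[has_m]]
      bg_ref[has_m] <- bg_ref[has_m] - counts$ref_count[m_act[has_m]]
    }
    p_raw <- fisher_alt_p(own_alt, own_ref, bg_alt, bg_ref)
    # emptied background: no evidence
    p_raw[bg_alt + bg_ref == 0] <- 1
    p_adj <- holm_adjust(p_raw)
    hit <- p_adj < retain_alpha
    logs[[iter]] <- data.frame(
      candidates[active, , drop = FALSE],
      alt_fg = own_alt, ref_fg = own_ref, alt_bg = bg_alt, ref_bg = bg_ref,
      p_raw = p_raw, p_adj = p_adj, iteration = iter, retained = hit,
      stringsAsFactors = FALSE, row.names = NULL)
    def_p_raw[active] <- p_raw
    def_p_adj[active] <- p_adj
    if (!any(hit)) break
    newly <- active[hit]
    retained[newly] <- TRUE
    ret_iter[newly] <- iter
  }
  results <- data.frame(candidates,
                        p_raw = def_p_raw, p_adj = def_p_adj,
                        iteration = ifelse(retained, ret_iter, iter),
                        retained = retained,
                        carried_forward = retained & def_p_adj <= final_alpha,
                        stringsAsFactors = FALSE, row.names = NULL)
  list(retained = results[results$retained, , drop = FALSE],
       results = results,
       log = do.call(rbind, logs))
}

#' Classify SNV validation outcomes
#'
#' Applies the pipeline's depth and significance gates to per-candidate
#' tumor and matched-normal statistics: sites with tumor error-corrected
#' depth below `min_validation_depth` (100) are `LOW_DEPTH`; with an
#' evaluable normal (depth >= 100), `PASS` requires tumor adjusted p at
#' or below `final_alpha` (0.05) and normal adjusted p above
#' `normal_alpha` (0.05); without an evaluable normal, `TUMOR_ONLY`
#' requires the tumor gate alone.  Everything else is `FAIL`; candidates
#' with no tumor data are `NOT_ASSAYED`.
#'
#' @param tumor_depth,tumor_p_adj Tumor error-corrected depth and
#'   definitive Holm-adjusted p (vectors).
#' @param normal_depth,normal_p_adj Matched-normal depth and adjusted p;
#'   NA when the normal was not assayed.
#' @param config A [pipeline_config()].
#' @return A data.frame with `status` in
#'   PASS / TUMOR_ONLY / FAIL / LOW_DEPTH / NOT_ASSAYED plus the input
#'   statistics.
#' @export
classify_snv <- function(tumor_depth, tumor_p_adj,
                         normal_depth = NA_real_, normal_p_adj = NA_real_,
                         config = pipeline_config()) {
  n <- max(length(tumor_depth), length(tumor_p_adj))
  tumor_depth <- rep_len(tumor_depth, n)
  tumor_p_adj <- rep_len(tumor_p_adj, n)
  normal_depth <- rep_len(normal_depth, n)
  normal_p_adj <- rep_len(normal_p_adj, n)
  status <- character(n)
  for (i in seq_len(n)) {
    status[i] <- if (is.na(tumor_depth[i])) {
      "NOT_ASSAYED"
    } else if (tumor_depth[i] < config$min_validation_depth) {
      "LOW_DEPTH"
    } else if (!is.na(normal_depth[i]) &&
               normal_depth[i] >= config$min_validation_depth) {
      if (!is.na(tumor_p_adj[i]) && tumor_p_adj[i] <= config$final_alpha &&
          !is.na(normal_p_adj[i]) && normal_p_adj[i] > config$normal_alpha)
        "PASS" else "FAIL"
    } else {
      if (!is.na(tumor_p_adj[i]) && tumor_p_adj[i] <= config$final_alpha)
        "TUMOR_ONLY" else "FAIL"
    }
  }
  data.frame(status = status, tumor_depth = tumor_depth,
             tumor_p_adj = tumor_p_adj, normal_depth = normal_depth,
             normal_p_adj = normal_p_adj, stringsAsFactors = FALSE)
}

#' Run SNV validation end to end for a tumor/normal cohort
#'
#' Convenience wrapper: runs [iterate_validation()] over the tumor
#' candidates together with their matched-normal (sample, site) pairs
#' (so the normal's own significance is estimated against the same
#' iteratively cleaned background), then applies [classify_snv()].
#'
#' @param counts Combined site count table over tumors and normals.
#' @param candidates Tumor candidate pairs (`sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`).
#' @param meta Sample metadata with `sample_id`, `patient_id`, `tissue`.
#' @param config A [pipeline_config()]; `exclude_matched_normal`
#'   controls whether each tumor's matched normal is kept out of its
#'   background pool.
#' @return A list: `outcomes` (one row per candidate with `status` and
#'   statistics) and `validation` (the [iterate_validation()] result).
#' @export
validate_snv_cohort <- function(counts, candidates, meta,
                                config = pipeline_config()) {
  stopifnot(all(c("sample_id", "patient_id", "tissue") %in% names(meta)))
  normal_of <- function(sid) {
    p <- meta$patient_id[match(sid, meta$sample_id)]
    hit <- meta$sample_id[meta$patient_id == p & meta$tissue == "normal"]
    if (length(hit)) hit[1] else NA_character_
  }
  nrm <- vapply(candidates$sample_id, normal_of, "")
  nrm[nrm == ""] <- NA_character_

  # matched-normal pairs that exist in the count table join the test set
  norm_cand <- candidates
  norm_cand$sample_id <- nrm
  norm_cand <- norm_cand[!is.na(norm_cand$sample_id), , drop = FALSE]
  norm_cand <- norm_cand[pair_key(norm_cand) %in% pair_key(counts), ,
                         drop = FALSE]
  norm_cand <- norm_cand[!duplicated(pair_key(norm_cand)), , drop = FALSE]
  all_cand <- rbind(candidates, norm_cand)
  all_cand <- all_cand[!duplicated(pair_key(all_cand)), , drop = FALSE]

  matched <- if (config$exclude_matched_normal) {
    m <- rep(NA_character_, nrow(all_cand))
    idx <- match(pair_key(candidates), pair_key(all_cand))
    m[idx] <- nrm
    m
  } else NULL

  val <- iterate_validation(counts, all_cand,
                            retain_alpha = config$retain_alpha,
                            final_alpha = config$final_alpha,
                            matched = matched)
  res <- val$results
  reskey <- pair_key(res)
  tidx <- match(pair_key(candidates), reskey)
  nkey <- ifelse(is.na(nrm), NA_character_,
                 paste(nrm, site_key(candidates), sep = "@"))
  nidx <- match(nkey, reskey)
  cntkey <- pair_key(counts)
  tdep <- counts$depth[match(pair_key(candidates), cntkey)]
  ndep <- counts$depth[match(nkey, cntkey)]
  outc <- classify_snv(tumor_depth = tdep, tumor_p_adj = res$p_adj[tidx],
                       normal_depth = ndep, normal_p_adj = res$p_adj[nidx],
                       config = config)
  outcomes <- data.frame(candidates, normal_sample = nrm, outc,
                         stringsAsFactors = FALSE, row.names = NULL)
  list(outcomes = outcomes, validation = val)
}
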