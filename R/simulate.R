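#' Background sequencing-error profile
#'
#' Describes the position-specific error floor of the assay: a per-site
#' background error rate and an overdispersion parameter governing how
#' much that rate varies between samples (library- and run-level
#' effects).  With `dispersion = 0` every sample sees exactly `rate`
#' (pure binomial noise); with `dispersion > 0` the per-sample rate is
#' drawn from a beta distribution with mean `rate` and concentration
#' `1 / dispersion`, so larger values mean noisier, more sample-variable
#' error (beta-binomial counts).
#'
#' @param rate Per-site background error rate(s), in `[0, 0.5)`; scalar
#'   or one per site.
#' @param dispersion Overdispersion, `>= 0`. Default 0.
#' @return A list of class `error_profile`.
#' @export
error_profile <- function(rate, dispersion = 0) {
  rate <- as.numeric(rate)
  if (any(rate < 0 | rate >= 0.5)) stop("rate must lie in [0, 0.5)")
  if (length(dispersion) != 1L || dispersion < 0)
    stop("dispersion must be a single nonnegative number")
  structure(list(rate = rate, dispersion = as.numeric(dispersion)),
            class = "error_profile")
}

#' Specify true variants to spike into a simulated cohort
#'
#' @param sample_id Sample carrying the variant.
#' @param site A [genomic_site()] data.frame (recycled against
#'   `sample_id`).
#' @param true_vaf True allele fraction of each spike; by default must
#'   lie in `(0, 0.25]`, the range over which low-VAF variants from rare
#'   malignant cells are observed (0.5%--24.1% in deep bulk biopsies).
#' @param max_vaf Upper bound enforced on `true_vaf`. Default 0.25; set
#'   to 1 to allow degenerate spikes.
#' @return A data.frame of spike specifications.
#' @export
spike_spec <- function(sample_id, site, true_vaf, max_vaf = 0.25) {
  true_vaf <- as.numeric(true_vaf)
  if (any(true_vaf <= 0 | true_vaf > max_vaf))
    stop("true_vaf must lie in (0, ", max_vaf, "]")
  data.frame(sample_id = as.character(sample_id),
             site[, c("chrom", "pos", "ref", "alt")],
             true_vaf = true_vaf, stringsAsFactors = FALSE)
}

#' Deterministic synthetic panel sites
#'
#' The default assay sites of [simulate_cohort_counts()]: evenly spaced
#' positions on a synthetic chromosome with reference alleles cycling
#' A/C/G/T and transition alternates.  Deterministic, so spike
#' specifications built from it remain valid for any simulation seed.
#'
#' @param n_sites Number of sites.
#' @return A [genomic_site()] data.frame.
#' @export
panel_sites <- function(n_sites) {
  ref <- rep_len(c("A", "C", "G", "T"), n_sites)
  alt <- c(A = "G", C = "T", G = "A", T = "C")[ref]
  genomic_site("chr1", seq_len(n_sites) * 10L, ref, unname(alt))
}

# beta-binomial (or binomial when dispersion == 0) alt counts
rbetabinom_ <- function(n, size, prob, dispersion) {
  prob <- rep_len(prob, n)
  zero <- prob <= 0
  out <- integer(n)
  if (all(zero)) return(out)
  idx <- which(!zero)
  if (dispersion > 0) {
    conc <- 1 / dispersion
    p <- rbeta(length(idx), conc * prob[idx], conc * (1 - prob[idx]))
  } else {
    p <- prob[idx]
  }
  out[idx] <- rbinom(length(idx), size[idx], p)
  out
}

#' Simulate error-corrected count tables for a tumor/normal cohort
#'
#' Generates per-(sample, site) consensus read counts with the
#' statistical structure the background-validation test assumes: depths
#' drawn from a negative binomial around the arm's mean (coverage in
#' capture panels is uneven), alt counts binomial (beta-binomial when the
#' profile is overdispersed) at each site's background error rate, plus
#' additional binomial variant-supporting reads at spiked (sample, site)
#' pairs.  Defaults emulate a deep amplicon validation experiment:
#' 30 tumor/normal pairs with median error-corrected depths near
#' 4,000x (tumor) and 2,000x (normal).
#'
#' @param n_pairs Number of tumor/normal pairs (>= 2; background pooling
#'   needs other samples). Default 30.
#' @param n_sites Number of assayed sites. Default 500.
#' @param mean_depth Mean consensus depth; length-2 vector
#'   `c(tumor, normal)` or a scalar used for both. Default
#'   `c(3971, 2168)`.
#' @param profile An [error_profile()]. Default rate 1e-3, dispersion 0.
#' @param spikes A [spike_spec()] data.frame of true variants, or NULL.
#' @param sites Site table to assay (defaults to [panel_sites]`(n_sites)`,
#'   which is deterministic so spike specifications compose across
#'   seeds).
#' @param depth_size Negative-binomial size (inverse dispersion) of the
#'   depth distribution. Default 20.
#' @param seed Integer seed; the whole simulation is reproducible given
#'   it.
#' @return A list with elements `tumor` and `normal` (site count tables,
#'   see [site_count_table()]), `truth` (per simulated (sample, site)
#'   pair, `true_variant` or `clean`), `sites` (the site table) and
#'   `meta` (sample metadata pairing tumors with normals).
#' @examples
#' sim <- simulate_cohort_counts(n_pairs = 4, n_sites = 20, seed = 1)
#' head(sim$tumor)
#' @export
simulate_cohort_counts <- function(n_pairs = 30L, n_sites = 500L,
                                   mean_depth = c(3971, 2168),
                                   profile = error_profile(1e-3),
                                   spikes = NULL, sites = NULL,
                                   depth_size = 20, seed = NULL) {
  if (n_pairs < 2L) stop("n_pairs must be >= 2")
  if (any(mean_depth <= 0)) stop("depths must be > 0")
  if (length(mean_depth) == 1L) mean_depth <- rep(mean_depth, 2L)
  stopifnot(inherits(profile, "error_profile"))
  rate <- rep_len(profile$rate, n_sites)
  if (!is.null(seed)) set.seed(as.integer(seed))

  pid <- sprintf("P%02d", seq_len(n_pairs))
  meta <- data.frame(
    sample_id = c(paste0(pid, "_T"), paste0(pid, "_N")),
    patient_id = rep(pid, 2L),
    tissue = rep(c("tumor", "normal"), each = n_pairs),
    stringsAsFactors = FALSE)

  if (is.null(sites)) sites <- panel_sites(n_sites)
  if (nrow(sites) != n_sites) stop("sites must have n_sites rows")

  if (!is.null(spikes) && nrow(spikes)) {
    if (!all(spikes$sample_id %in% meta$sample_id))
      stop("spike references unknown sample: ",
           paste(setdiff(spikes$sample_id, meta$sample_id), collapse = ", "))
    if (!all(site_key(spikes) %in% site_key(sites)))
      stop("spike references unknown site")
  }

  one_arm <- function(samples, mu) {
    grid <- data.frame(
      sample_id = rep(samples, each = n_sites),
      sites[rep(seq_len(n_sites), length(samples)), ],
      stringsAsFactors = FALSE, row.names = NULL)
    nrow_ <- nrow(grid)
    depth <- pmax(1L, rnbinom(nrow_, size = depth_size, mu = mu))
    err_rate <- rep(rate, length(samples))
    alt_err <- rbetabinom_(nrow_, depth, err_rate, profile$dispersion)
    grid$depth_sim <- depth
    grid$alt_count <- alt_err
    grid
  }

  tumor <- one_arm(meta$sample_id[meta$tissue == "tumor"], mean_depth[1])
  normal <- one_arm(meta$sample_id[meta$tissue == "normal"], mean_depth[2])

  add_spikes <- function(grid) {
    if (is.null(spikes) || !nrow(spikes)) return(grid)
    key <- pair_key(grid)
    skey <- pair_key(spikes)
    hit <- match(skey, key)
    ok <- !is.na(hit)
    if (any(ok)) {
      extra <- rbinom(sum(ok), grid$depth_sim[hit[ok]], spikes$true_vaf[ok])
      grid$alt_count[hit[ok]] <- pmin(grid$depth_sim[hit[ok]],
                                      grid$alt_count[hit[ok]] + extra)
    }
    grid
  }
  tumor <- add_spikes(tumor)
  normal <- add_spikes(normal)

  finish <- function(grid) {
    grid$ref_count <- grid$depth_sim - grid$alt_count
    grid$other_count <- 0L
    site_count_table(grid[, c("sample_id", "chrom", "pos", "ref", "alt",
                              "ref_count", "alt_count", "other_count")])
  }
  tumor <- finish(tumor); normal <- finish(normal)

  truth <- rbind(tumor[, c("sample_id", "chrom", "pos", "ref", "alt")],
                 normal[, c("sample_id", "chrom", "pos", "ref", "alt")])
  truth$status <- "clean"
  if (!is.null(spikes) && nrow(spikes))
    truth$status[pair_key(truth) %in% pair_key(spikes)] <- "true_variant"

  list(tumor = tumor, normal = normal, truth = truth, sites = sites,
       meta = meta)
}

#' Simulate UMI read families
#'
#' Each family carries a unique UMI; each member read copies the true
#' base string with every position flipped independently to one of the
#' other three bases at `error_rate`.
#'
#' @param n_families Number of families.
#' @param family_size_dist Family sizes: a single integer, an integer
#'   vector sampled uniformly with replacement, or a function of `n`
#'   returning `n` sizes.
#' @param true_base True base string shared by the families (length 1
#'   for single-site fixtures; longer strings give multi-site reads).
#' @param error_rate Per-base flip probability, `< 0.5`.
#' @param chrom,start Alignment coordinates of the families.
#' @param mapq,nm Mapping quality and mismatch count assigned to every
#'   read. Defaults 60 and 0.
#' @param seed Integer seed.
#' @return A tagged-read data.frame (see [read_tagged_reads()]) with
#'   attributes `true_base` and `n_families`.
#' @export
simulate_read_families <- function(n_families, family_size_dist,
                                   true_base = "A", error_rate = 0,
                                   chrom = "chr1", start = 1L,
                                   mapq = 60L, nm = 0L, seed = NULL) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sizes <- if (is.function(family_size_dist)) {
    as.integer(family_size_dist(n_families))
  } else if (length(family_size_dist) == 1L) {
    rep(as.integer(family_size_dist), n_families)
  } else {
    sample(as.integer(family_size_dist), n_families, replace = TRUE)
  }
  if (any(sizes < 1L)) stop("family sizes must be >= 1")
  tmpl <- strsplit(toupper(true_base), "")[[1]]
  L <- length(tmpl)
  n_reads <- sum(sizes)
  mat <- matrix(rep(tmpl, n_reads), nrow = n_reads, byrow = TRUE)
  if (error_rate > 0) {
    flip <- matrix(stats::runif(n_reads * L) < error_rate, nrow = n_reads)
    if (any(flip)) {
      others <- lapply(tmpl, function(b) setdiff(c("A", "C", "G", "T"), b))
      for (j in seq_len(L)) {
        idx <- which(flip[, j])
        if (length(idx))
          mat[idx, j] <- sample(others[[j]], length(idx), replace = TRUE)
      }
    }
  }
  bases <- apply(mat, 1L, paste, collapse = "")
  out <- data.frame(
    umi = rep(sprintf("UMI%06d", seq_len(n_families)), times = sizes),
    chrom = chrom, start = as.integer(start), bases = bases,
    mapq = as.integer(mapq), nm = as.integer(nm),
    stringsAsFactors = FALSE)
  attr(out, "true_base") <- toupper(true_base)
  attr(out, "n_families") <- n_families
  out
}

#' Simulate a gene sequence with a target AID-motif density
#'
#' Builds a nucleotide sequence whose fraction of WRC/GYW motif positions
#' (as reported by [scan_motifs()]) lies within `tol` of
#' `target_motif_fraction`.  The sequence starts from an A/T background
#' (motif-free) and motif trinucleotides are planted at random positions,
#' alternating WRC- and GYW-forming plants for strand balance, until the
#' scanned fraction reaches the target.
#'
#' @param length Sequence length in bp (>= 3).
#' @param target_motif_fraction Desired motif-position fraction; the
#'   achievable maximum with this construction is about 1/3.
#' @param tol Acceptable absolute deviation. Default 0.02.
#' @param max_tries Bounded retries before giving up. Default 50.
#' @param seed Integer seed; the same seed yields the same sequence.
#' @return A single character string.
#' @export
simulate_gene_with_motifs <- function(length, target_motif_fraction,
                                      tol = 0.02, max_tries = 50L,
                                      seed = NULL) {
  if (length < 3L) stop("length must be >= 3")
  if (target_motif_fraction < 0 || target_motif_fraction > 0.34)
    stop("target_motif_fraction must lie in [0, ~1/3]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  seq_ <- sample(c("A", "T"), length, replace = TRUE)
  if (target_motif_fraction == 0) return(paste(seq_, collapse = ""))
  target_n <- round(target_motif_fraction * length)
  wrc <- c("AAC", "TAC", "AGC", "TGC")  # W R C
  gyw <- c("GCA", "GCT", "GTA", "GTT")  # G Y W
  use_wrc <- TRUE
  for (try in seq_len(max_tries)) {
    got <- length(scan_motifs(paste(seq_, collapse = ""))$motif_positions)
    if (abs(got / length - target_motif_fraction) <= tol)
      return(paste(seq_, collapse = ""))
    need <- target_n - got
    if (need > 0) {
      for (i in seq_len(need)) {
        p <- sample.int(length - 2L, 1L)
        tri <- if (use_wrc) sample(wrc, 1L) else sample(gyw, 1L)
        seq_[p:(p + 2L)] <- strsplit(tri, "")[[1]]
        use_wrc <- !use_wrc
      }
    } else {
      # too many: erase surplus motifs by overwriting with A/T
      idx <- scan_motifs(paste(seq_, collapse = ""))$motif_positions
      kill <- sample(idx, min(length(idx), -need))
      seq_[kill] <- sample(c("A", "T"), length(kill), replace = TRUE)
    }
  }
  stop("could not reach target motif fraction ", target_motif_fraction,
       " within ", max_tries, " attempts")
}

#' Simulate mutation positions with AID-motif bias
#'
#' Places `n_mut` distinct mutations on a sequence, weighting motif
#' positions by `motif_bias` relative to non-motif positions (bias 1 is
#' uniform placement; large bias concentrates mutations in WRC/GYW
#' motifs, emulating aberrant AID activity).
#'
#' @param seq A nucleotide string.
#' @param n_mut Number of distinct positions to mutate (`<=` sequence
#'   length).
#' @param motif_bias Relative sampling weight of motif positions, `>= 1`.
#' @param seed Integer seed.
#' @return Sorted integer vector of 1-based positions.
#' @export
simulate_aid_mutations <- function(seq, n_mut, motif_bias = 1, seed = NULL) {
  n <- nchar(seq)
  if (n_mut > n) stop("n_mut exceeds the number of positions")
  if (motif_bias < 1) stop("motif_bias must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  idx <- scan_motifs(seq)
  w <- rep(1, n)
  w[idx$motif_positions] <- motif_bias
  sort(sample.int(n, n_mut, prob = w))
}
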