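#' Detect runs of homozygosity from an ordered genotype series
#'
#' Slides a window of `window_sites` consecutive sites along one sample's
#' genotypes on one chromosome and flags windows containing at most
#' `max_het_per_window` heterozygous calls. Overlapping flagged windows are
#' merged; merged regions shorter than `min_length_mb` or containing fewer
#' than `min_sites` sites, or exceeding `max_het_fraction` heterozygosity,
#' are discarded. Site-count windows (rather than physical-length windows)
#' keep the detector robust to variant-density variation. Defaults
#' comfortably detect ROH at the multi-megabase scale relevant to
#' consanguinity (e.g. 9-20 Mb) and are configurable.
#'
#' @param sites Data frame with columns `pos` (sorted ascending) and `gt`
#'   (genotype strings or allele counts; only het vs non-het matters).
#' @param window_sites Window size in sites (default 50).
#' @param max_het_per_window Maximum heterozygous sites per flagged window
#'   (default 2).
#' @param min_length_mb Minimum region length in Mb (default 2).
#' @param min_sites Minimum sites per region (default 100).
#' @param max_het_fraction Maximum heterozygote fraction within a reported
#'   region (default 0.05).
#' @param het_penalty Boundary refinement: window-flagged regions
#'   over-extend into flanking sequence (windows straddling a block edge
#'   tolerate a few heterozygotes), so each merged region is re-bounded by
#'   a score scan outward from its interior - each homozygous site scores
#'   +1, each heterozygous site scores `-het_penalty` - and the boundary is
#'   placed at the outward score maximum. The default of 9 corresponds to
#'   the log-likelihood ratio of genotype heterozygosity inside a true ROH
#'   (genotyping error, ~0.5%) versus outside (common biallelic markers,
#'   ~40%); a boundary therefore only extends across a heterozygous site
#'   when at least nine homozygous sites follow it.
#' @return Tibble of regions: `start`, `end`, `n_sites`, `n_het`.
#' @export
detect_roh <- function(sites, window_sites = 50, max_het_per_window = 2,
                       min_length_mb = 2, min_sites = 100,
                       max_het_fraction = 0.05, het_penalty = 9) {
  stopifnot(is.data.frame(sites), all(c("pos", "gt") %in% names(sites)))
  empty <- tibble::tibble(start = integer(), end = integer(),
                          n_sites = integer(), n_het = integer())
  n <- nrow(sites)
  if (n == 0) return(empty)
  if (is.unsorted(sites$pos)) stop("detect_roh() requires sites sorted by position", call. = FALSE)
  het <- as.integer(gt_code(sites$gt) == 1L)
  het[is.na(het)] <- 0L
  if (n < window_sites) return(empty)
  win_het <- zoo::rollsum(het, k = window_sites, align = "left")
  flagged_start <- which(win_het <= max_het_per_window)
  if (length(flagged_start) == 0) return(empty)
  # mark all sites covered by any flagged window, then extract runs
  covered <- logical(n)
  for (i in flagged_start) covered[i:(i + window_sites - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  refine <- function(idx) {
    m <- length(idx)
    sc <- ifelse(het[idx] == 1L, -het_penalty, 1L)
    mid <- (m + 1L) %/% 2L
    cum_l <- cumsum(sc[rev(seq_len(mid))])
    lo <- mid - which.max(cum_l) + 1L
    hi <- mid
    if (m > mid) {
      cum_r <- cumsum(sc[seq.int(mid + 1L, m)])
      if (max(cum_r) > 0) hi <- mid + which.max(cum_r)
    }
    idx[lo:hi]
  }
  regions <- purrr::map(keep, function(k) {
    idx <- refine(starts[k]:ends[k])
    tibble::tibble(
      start = sites$pos[idx[1]], end = sites$pos[idx[length(idx)]],
      n_sites = length(idx), n_het = sum(het[idx])
    )
  })
  out <- purrr::list_rbind(regions)
  dplyr::filter(
    out,
    (.data$end - .data$start + 1) >= min_length_mb * 1e6,
    .data$n_sites >= min_sites,
    .data$n_het / .data$n_sites <= max_het_fraction
  )
}

#' Detect ROH for one sample across all chromosomes of a variant table
#'
#' Convenience wrapper around [detect_roh()]: extracts the sample's
#' genotypes from a variant table + genotype matrix and runs the detector
#' per chromosome.
#'
#' @param variants Variant tibble with `variant_id`, `chrom`, `pos`.
#' @param gt Genotype matrix (variants x samples, allele counts; rownames
#'   are `variant_id`, colnames sample ids).
#' @param sample_id Sample to scan.
#' @param ... Passed to [detect_roh()].
#' @return Tibble of regions with a leading `chrom` column.
#' @export
roh_for_sample <- function(variants, gt, sample_id, ...) {
  stopifnot(sample_id %in% colnames(gt))
  idx_by_chrom <- split(seq_len(nrow(variants)), variants$chrom)
  out <- purrr::list_rbind(purrr::imap(idx_by_chrom, function(idx, ch) {
    o <- idx[order(variants$pos[idx])]
    r <- detect_roh(tibble::tibble(pos = variants$pos[o],
                                   gt = gt[o, sample_id]), ...)
    if (nrow(r) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(chrom = ch), r)
  }))
  if (is.null(out) || nrow(out) == 0) {
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   n_sites = integer(), n_het = integer())
  } else {
    out
  }
}

#' The ROH region fully containing a locus
#'
#' @param regions ROH tibble with `chrom`, `start`, `end` (e.g. from
#'   [roh_for_sample()]).
#' @param locus One-row data frame (or list) with `chrom`, `start`, `end`.
#' @return The single containing region (the longest, if several) as a
#'   one-row tibble, or a zero-row tibble when no region fully contains the
#'   locus.
#' @export
containing_roh <- function(regions, locus) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_sites = integer(), n_het = integer()))
  }
  hit <- dplyr::filter(regions, interval_contains(
    .data$chrom, .data$start, .data$end, locus$chrom, locus$start, locus$end))
  if (nrow(hit) == 0) return(hit)
  dplyr::slice_max(hit, .data$end - .data$start, n = 1, with_ties = FALSE)
}
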