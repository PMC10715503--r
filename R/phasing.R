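# Genotypes are handled as alternate-allele counts: 0 (hom ref), 1 (het),
# 2 (hom alt), NA (missing). gt_code() converts the usual VCF strings.

#' Convert VCF-style genotype strings to alternate-allele counts
#'
#' @param gt Character vector such as `"0/1"`, `"1|1"`, `"./."`, or an
#'   already-numeric vector of counts (returned unchanged, validated).
#' @return Integer vector with values 0, 1, 2 or `NA`.
#' @export
gt_code <- function(gt) {
  if (is.numeric(gt)) {
    g <- as.integer(gt)
    if (any(!is.na(g) & (g < 0L | g > 2L))) stop("genotype counts must be 0, 1 or 2", call. = FALSE)
    return(g)
  }
  g <- gsub("\\|", "/", as.character(gt))
  out <- dplyr::case_when(
    g %in% c("0/0") ~ 0L,
    g %in% c("0/1", "1/0") ~ 1L,
    g %in% c("1/1") ~ 2L,
    TRUE ~ NA_integer_
  )
  out
}

#' Parental origin of a variant carried by a proband
#'
#' Inheritance assignment from trio genotypes alone (no read-backed
#' phasing): a variant is called maternal when the mother carries it and the
#' father does not, paternal in the symmetric case, de novo when neither
#' parent carries it, ambiguous when both do, and unknown when a parental
#' genotype is missing.
#'
#' @param proband_gt,mother_gt,father_gt Genotypes (strings or allele
#'   counts, see [gt_code()]); the proband must be non-reference.
#' @return One of `"MATERNAL"`, `"PATERNAL"`, `"DE_NOVO"`, `"AMBIGUOUS"`,
#'   `"UNKNOWN_NO_TRIO"` (vectorised).
#' @examples
#' inherited_from("0/1", "0/1", "0/0") # MATERNAL
#' @export
inherited_from <- function(proband_gt, mother_gt, father_gt) {
  p <- gt_code(proband_gt); m <- gt_code(mother_gt); f <- gt_code(father_gt)
  if (any(is.na(p)) || any(p == 0L)) {
    stop("inherited_from() requires a non-reference proband genotype", call. = FALSE)
  }
  dplyr::case_when(
    is.na(m) | is.na(f) ~ "UNKNOWN_NO_TRIO",
    m > 0L & f == 0L ~ "MATERNAL",
    f > 0L & m == 0L ~ "PATERNAL",
    m == 0L & f == 0L ~ "DE_NOVO",
    TRUE ~ "AMBIGUOUS"
  )
}

#' Phase of a candidate pair from two inheritance calls
#'
#' Two variants are in trans (compound heterozygous) when one is maternal
#' and the other paternal, in cis when both have the same parental origin,
#' and unknown whenever either origin is ambiguous, de novo or missing.
#' Symmetric in its arguments.
#'
#' @param origin_a,origin_b Inheritance calls from [inherited_from()].
#' @return One of `"TRANS"`, `"CIS"`, `"UNKNOWN"` (vectorised).
#' @examples
#' phase_pair("MATERNAL", "PATERNAL") # TRANS
#' @export
phase_pair <- function(origin_a, origin_b) {
  parental <- c("MATERNAL", "PATERNAL")
  dplyr::case_when(
    origin_a %in% parental & origin_b %in% parental & origin_a != origin_b ~ "TRANS",
    origin_a %in% parental & origin_a == origin_b ~ "CIS",
    TRUE ~ "UNKNOWN"
  )
}

#' Mosaic cell fraction of a deletion from read depth
#'
#' A heterozygous deletion present in a fraction f of cells reduces the
#' expected read depth over the deleted region to `flank * (1 - f/2)`, so
#' `f = 2 * (1 - depth_in / depth_flank)`, clamped to \[0, 1\] and reported
#' as a percentage. A constitutively heterozygous deletion (depth ratio 0.5)
#' therefore reads as 100%. Intended for deletions only.
#'
#' @param depth_in Mean read depth over the deleted region.
#' @param depth_flank Mean read depth over flanking sequence; must be > 0.
#' @return Percentage of cells carrying the heterozygous deletion, in
#'   \[0, 100\] (vectorised).
#' @examples
#' mosaic_fraction(39, 50) # 44
#' mosaic_fraction(30, 60) # 100 (constitutive het)
#' @export
mosaic_fraction <- function(depth_in, depth_flank) {
  if (any(depth_flank <= 0)) stop("depth_flank must be > 0", call. = FALSE)
  f <- 2 * (1 - depth_in / depth_flank)
  100 * pmin(pmax(f, 0), 1)
}

#' Mendelian consistency of a trio genotype
#'
#' @param proband_gt,mother_gt,father_gt Genotypes (strings or counts); all
#'   three must be present.
#' @return Logical: can the proband's alleles be drawn one from each parent?
#' @examples
#' mendelian_consistent("0/1", "0/1", "0/0") # TRUE
#' mendelian_consistent("1/1", "0/0", "0/0") # FALSE
#' @export
mendelian_consistent <- function(proband_gt, mother_gt, father_gt) {
  p <- gt_code(proband_gt); m <- gt_code(mother_gt); f <- gt_code(father_gt)
  if (any(is.na(p) | is.na(m) | is.na(f))) {
    stop("mendelian_consistent() requires all three genotypes present", call. = FALSE)
  }
  # which alleles each parent can transmit
  can_ref <- function(g) g < 2L
  can_alt <- function(g) g > 0L
  dplyr::case_when(
    p == 0L ~ can_ref(m) & can_ref(f),
    p == 2L ~ can_alt(m) & can_alt(f),
    TRUE ~ (can_ref(m) & can_alt(f)) | (can_alt(m) & can_ref(f))
  )
}

#' Estimate a sample's mosaic deletion fraction from a depth table
#'
#' Splits a per-region mean-depth table into the deleted region and its
#' flanks. Depth rows whose midpoint lies inside the SV count as in-SV
#' depth; rows outside count as flank, excluding a guard zone around each
#' breakpoint (reads near breakpoints are unreliable) and limiting the flank
#' to a window of the SV's own length on each side. Means are weighted by
#' row length.
#'
#' @param depth Depth table: `sample_id`, `chrom`, `start`, `end`,
#'   `mean_depth` (one row per summarised window).
#' @param sample_id Sample to estimate.
#' @param sv One-row data frame (or list) with `chrom`, `start`, `end` of
#'   the deletion.
#' @param guard_bp Breakpoint guard zone excluded from the flank (default 1 kb).
#' @param flank_bp Flank window on each side; defaults to the SV length.
#' @return One-row tibble: `sample_id`, `depth_in`, `depth_flank`,
#'   `fraction_pct` (or `NA`s when no informative rows exist).
#' @export
estimate_mosaic <- function(depth, sample_id, sv, guard_bp = 1000,
                            flank_bp = NULL) {
  sv_len <- as.numeric(sv$end) - as.numeric(sv$start) + 1
  if (is.null(flank_bp)) flank_bp <- sv_len
  d <- dplyr::filter(depth, .data$sample_id == .env$sample_id,
                     .data$chrom == sv$chrom)
  if (nrow(d) == 0) {
    return(tibble::tibble(sample_id = sample_id, depth_in = NA_real_,
                          depth_flank = NA_real_, fraction_pct = NA_real_))
  }
  mid <- (d$start + d$end) / 2
  w <- d$end - d$start + 1
  inside <- mid >= sv$start & mid <= sv$end
  in_flank <- !inside &
    ((mid < sv$start & mid <= sv$start - guard_bp & mid >= sv$start - guard_bp - flank_bp) |
     (mid > sv$end & mid >= sv$end + guard_bp & mid <= sv$end + guard_bp + flank_bp))
  if (!any(inside) || !any(in_flank)) {
    return(tibble::tibble(sample_id = sample_id, depth_in = NA_real_,
                          depth_flank = NA_real_, fraction_pct = NA_real_))
  }
  depth_in <- stats::weighted.mean(d$mean_depth[inside], w[inside])
  depth_flank <- stats::weighted.mean(d$mean_depth[in_flank], w[in_flank])
  tibble::tibble(sample_id = sample_id, depth_in = depth_in,
                 depth_flank = depth_flank,
                 fraction_pct = mosaic_fraction(depth_in, depth_flank))
}
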