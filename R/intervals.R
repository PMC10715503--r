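#' Construct a tibble of genomic intervals
#'
#' Intervals are 1-based and inclusive at both ends (the VCF/HGVS convention
#' used throughout the package); BED input/output converts at the boundary.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 1-based inclusive positions;
#'   `start >= 1` and `end >= start` are enforced.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr2", 135165337, 135511837)
#' @export
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 1L)) stop("interval start must be >= 1", call. = FALSE)
  if (any(end < start)) stop("interval end must be >= start", call. = FALSE)
  tibble::tibble(chrom = as.character(chrom), start = start, end = end)
}

#' Interval length in base pairs (inclusive)
#'
#' @param start,end 1-based inclusive coordinates.
#' @return `end - start + 1`.
#' @export
interval_length <- function(start, end) {
  as.numeric(end) - as.numeric(start) + 1
}

#' Span of an interval in kilobases
#'
#' Reports the coordinate difference `(end - start) / 1000` rounded to one
#' decimal place. This is the convention used when quoting SV sizes from
#' printed breakpoint coordinates (the difference of the two printed
#' positions, not the inclusive length), e.g. chr2:135,165,337-135,511,837
#' is quoted as a 346.5 kb deletion.
#'
#' @param start,end 1-based coordinates (vectors recycle).
#' @return Numeric vector of spans in kb, one decimal place.
#' @examples
#' span_kb(135165337, 135511837) # 346.5
#' @export
span_kb <- function(start, end) {
  round((as.numeric(end) - as.numeric(start)) / 1000, 1)
}

#' Reciprocal overlap of two intervals
#'
#' Overlap length divided by the length of the *longer* interval, the
#' standard SV-equivalence criterion: two observations of the same SV with
#' slightly different breakpoints score close to 1, while nested intervals
#' of very different size score low. Vectorised; intervals on different
#' chromosomes score 0 by contract.
#'
#' @param chrom_a,start_a,end_a First interval (1-based inclusive).
#' @param chrom_b,start_b,end_b Second interval.
#' @return Numeric fraction in \[0, 1\].
#' @examples
#' reciprocal_overlap("chr1", 1001, 2000, "chr1", 1101, 2100) # 0.9
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  ov <- pmin(as.numeric(end_a), as.numeric(end_b)) -
    pmax(as.numeric(start_a), as.numeric(start_b)) + 1
  ov <- pmax(ov, 0)
  longer <- pmax(interval_length(start_a, end_a), interval_length(start_b, end_b))
  out <- ov / longer
  out[as.character(chrom_a) != as.character(chrom_b)] <- 0
  out
}

#' Does interval a fully contain interval b?
#' @noRd
interval_contains <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  as.character(chrom_a) == as.character(chrom_b) &
    as.numeric(start_a) <= as.numeric(start_b) &
    as.numeric(end_a) >= as.numeric(end_b)
}

#' Do two intervals intersect (same chromosome)?
#' @noRd
interval_intersects <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  as.character(chrom_a) == as.character(chrom_b) &
    as.numeric(start_a) <= as.numeric(end_b) &
    as.numeric(end_a) >= as.numeric(start_b)
}
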