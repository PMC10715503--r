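#' Length of intronic sequence retained by a gained splice acceptor
#'
#' A variant at intronic offset -k (HGVS `c.X-kREF>ALT`, with k >= 3) that
#' creates a new splice acceptor whose AG dinucleotide ends at position -k
#' causes inclusion of intronic positions -(k-1) ... -1 in the transcript,
#' i.e. `|offset| - 1` nucleotides. Offsets -1 and -2 are the canonical
#' acceptor dinucleotide itself and belong to a different variant category,
#' so they are rejected.
#'
#' @param offset Negative integer intronic offset, `<= -3`.
#' @return Integer count of retained intronic nucleotides.
#' @examples
#' acceptor_gain_retention(-26) # 25
#' @export
acceptor_gain_retention <- function(offset) {
  offset <- as.integer(offset)
  if (any(is.na(offset)) || any(offset > -3L)) {
    stop("acceptor-gain offset must be <= -3 (offsets -1/-2 are the canonical acceptor site)",
         call. = FALSE)
  }
  abs(offset) - 1L
}

#' Length of an included pseudoexon
#'
#' @param first_pos,last_pos Genomic (or intronic) positions of the first and
#'   last included base, `last_pos >= first_pos`.
#' @return Inclusive length `last_pos - first_pos + 1`.
#' @examples
#' pseudoexon_length(1000, 1124) # 125
#' @export
pseudoexon_length <- function(first_pos, last_pos) {
  first_pos <- as.integer(first_pos)
  last_pos <- as.integer(last_pos)
  if (any(last_pos < first_pos)) stop("last_pos must be >= first_pos", call. = FALSE)
  last_pos - first_pos + 1L
}

#' Does an inserted/removed length shift the reading frame?
#'
#' @param n_nt Non-negative count of inserted or removed coding nucleotides.
#' @return Logical; `TRUE` when `n_nt` is not a multiple of 3.
#' @examples
#' frameshift(73) # TRUE
#' frameshift(72) # FALSE
#' @export
frameshift <- function(n_nt) {
  n_nt <- as.integer(n_nt)
  if (any(n_nt < 0L)) stop("n_nt must be >= 0", call. = FALSE)
  n_nt %% 3L != 0L
}

#' Coding consequence of skipping an exon
#'
#' Given the cDNA coordinates of a skipped exon (e.g. `c.11023_11095del`),
#' returns the number of removed nucleotides and whether the removal shifts
#' the reading frame. Protein-level naming (the `fs*N` termination offset)
#' requires the transcript sequence and is deliberately not produced.
#'
#' @param c_start,c_end cDNA coordinates of the skipped exon, `1 <= c_start <= c_end`.
#' @return A tibble with columns `removed_nt` and `frameshift`.
#' @examples
#' exon_skip_consequence(11023, 11095) # 73 nt, frameshift
#' @export
exon_skip_consequence <- function(c_start, c_end) {
  c_start <- as.integer(c_start)
  c_end <- as.integer(c_end)
  if (any(c_start < 1L)) stop("c_start must be >= 1", call. = FALSE)
  if (any(c_end < c_start)) stop("c_end must be >= c_start", call. = FALSE)
  n <- c_end - c_start + 1L
  tibble::tibble(removed_nt = n, frameshift = frameshift(n))
}

#' Parse the restricted set of HGVS cDNA patterns used for splice arithmetic
#'
#' Supports exactly three shapes (hyphen, en-dash and minus-sign characters
#' are all accepted as the intronic offset separator):
#' \itemize{
#'   \item `c.POS-OFFSETREF>ALT` - intronic substitution upstream of an
#'     acceptor, e.g. `c.3140-26A>G`;
#'   \item `c.START_ENDdel` - deletion / exon skip, e.g. `c.11023_11095del`;
#'   \item `c.START_ENDinsN` - insertion of N nucleotides, e.g.
#'     `c.2848_2849ins1591`.
#' }
#' Anything else is rejected with an informative error.
#'
#' @param hgvs_c Character vector of cDNA HGVS strings.
#' @return A tibble with one row per input: `hgvs_c`, `kind`
#'   (`"intronic_sub"`, `"del"`, `"ins"`), `c_start`, `c_end`, `offset`
#'   (negative integer, intronic subs only), `ref`, `alt`, `ins_length`.
#' @examples
#' parse_splice_hgvs("c.3140-26A>G")
#' @export
parse_splice_hgvs <- function(hgvs_c) {
  norm <- gsub("[−–—]", "-", as.character(hgvs_c))
  one <- function(x, raw) {
    m <- stringr::str_match(x, "^c\\.(\\d+)-(\\d+)([ACGT])>([ACGT])$")
    if (!is.na(m[1, 1])) {
      return(tibble::tibble(
        hgvs_c = raw, kind = "intronic_sub",
        c_start = as.integer(m[1, 2]), c_end = as.integer(m[1, 2]),
        offset = -as.integer(m[1, 3]), ref = m[1, 4], alt = m[1, 5],
        ins_length = NA_integer_
      ))
    }
    m <- stringr::str_match(x, "^c\\.(\\d+)_(\\d+)del$")
    if (!is.na(m[1, 1])) {
      s <- as.integer(m[1, 2]); e <- as.integer(m[1, 3])
      if (e < s) stop("malformed HGVS range (end < start): ", raw, call. = FALSE)
      return(tibble::tibble(
        hgvs_c = raw, kind = "del", c_start = s, c_end = e,
        offset = NA_integer_, ref = NA_character_, alt = NA_character_,
        ins_length = NA_integer_
      ))
    }
    m <- stringr::str_match(x, "^c\\.(\\d+)_(\\d+)ins(\\d+)$")
    if (!is.na(m[1, 1])) {
      return(tibble::tibble(
        hgvs_c = raw, kind = "ins",
        c_start = as.integer(m[1, 2]), c_end = as.integer(m[1, 3]),
        offset = NA_integer_, ref = NA_character_, alt = NA_character_,
        ins_length = as.integer(m[1, 4])
      ))
    }
    stop("unsupported HGVS pattern: ", raw,
         " (supported: c.POS-OFFSETREF>ALT, c.START_ENDdel, c.START_ENDinsN)",
         call. = FALSE)
  }
  purrr::list_rbind(purrr::map2(norm, as.character(hgvs_c), one))
}

#' Splice consequence of a parsed variant
#'
#' Dispatches the length/frame arithmetic on the output of
#' [parse_splice_hgvs()]: intronic substitutions are interpreted as gained
#' acceptors (retained intronic sequence of `|offset| - 1` nt), deletions as
#' exon skips, insertions by their inserted length.
#'
#' @param parsed One-row tibble from [parse_splice_hgvs()] (or a data frame
#'   of several rows, processed rowwise).
#' @return A tibble with `hgvs_c`, `kind`, `altered_nt`, `frameshift`.
#' @export
splice_consequence <- function(parsed) {
  stopifnot(is.data.frame(parsed))
  n <- integer(nrow(parsed))
  is_sub <- parsed$kind == "intronic_sub"
  is_del <- parsed$kind == "del"
  is_ins <- parsed$kind == "ins"
  if (any(is_sub)) n[is_sub] <- acceptor_gain_retention(parsed$offset[is_sub])
  n[is_del] <- parsed$c_end[is_del] - parsed$c_start[is_del] + 1L
  n[is_ins] <- parsed$ins_length[is_ins]
  tibble::tibble(
    hgvs_c = parsed$hgvs_c, kind = parsed$kind,
    altered_nt = n, frameshift = frameshift(n)
  )
}
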