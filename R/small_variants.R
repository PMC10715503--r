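# Small-variant prioritisation. Variant tables carry one row per
# bi-allelic variant with annotation columns af_1000g, af_gnomad,
# af_cohort, cadd_phred and SpliceAI-style delta scores ag, al, dg, dl;
# genotypes live in a variants x samples allele-count matrix.

#' Evidence weights and thresholds for small-variant prioritisation
#'
#' Population allele frequency is the only hard filter; CADD and splice
#' delta scores are *ranking evidence only* - a causal variant can score
#' very low on both (deep-intronic splice variants with near-zero predicted
#' acceptor gain have been proven pathogenic by RNA studies), so a low
#' score must never exclude a candidate.
#'
#' @param af_rare_threshold Every population AF present must be strictly
#'   below this for a variant to be kept (default 0.01; mirrors the SV
#'   rarity threshold). Absent AFs are treated as 0 (novel).
#' @param cadd_weight,splice_max_delta_weight Non-negative weights in the
#'   ranking score (defaults 1 each).
#' @return Named list of weights.
#' @export
evidence_weights <- function(af_rare_threshold = 0.01, cadd_weight = 1,
                             splice_max_delta_weight = 1) {
  stopifnot(af_rare_threshold > 0, af_rare_threshold <= 1,
            cadd_weight >= 0, splice_max_delta_weight >= 0)
  list(af_rare_threshold = af_rare_threshold, cadd_weight = cadd_weight,
       splice_max_delta_weight = splice_max_delta_weight)
}

#' Ranking score of small variants
#'
#' `cadd_weight * cadd_phred + splice_max_delta_weight * max(ag, al, dg, dl)`,
#' with absent annotations contributing 0. Used for ordering candidate
#' lists only; never as an exclusion filter.
#'
#' @param variants Variant tibble (annotation columns optional; absent
#'   columns contribute 0).
#' @param weights From [evidence_weights()].
#' @return Numeric score per row.
#' @examples
#' ranking_score(tibble::tibble(cadd_phred = 18.5, ag = 0.99)) # 19.49
#' @export
ranking_score <- function(variants, weights = evidence_weights()) {
  n <- nrow(variants)
  col0 <- function(nm) {
    if (nm %in% names(variants)) {
      v <- variants[[nm]]
      ifelse(is.na(v), 0, v)
    } else {
      rep(0, n)
    }
  }
  max_delta <- pmax(col0("ag"), col0("al"), col0("dg"), col0("dl"))
  weights$cadd_weight * col0("cadd_phred") +
    weights$splice_max_delta_weight * max_delta
}

#' Rare small variants carried by one sample
#'
#' Keeps the variants at which `sample_id` has a non-reference genotype and
#' every *present* population AF (`af_1000g`, `af_gnomad`, `af_cohort`) is
#' strictly below the rarity threshold; an absent AF is treated as 0
#' (novel, e.g. a variant kept purely because it is missing from the
#' population databases). Output is sorted by descending ranking score -
#' evidence scores reorder but never remove variants.
#'
#' @param variants Variant tibble with `variant_id` and annotation columns.
#' @param gt Allele-count genotype matrix (variants x samples; rownames
#'   `variant_id`).
#' @param sample_id Sample whose carried variants are wanted.
#' @param weights From [evidence_weights()].
#' @return The rare carried subset with a `rank_score` column, sorted by
#'   descending score (ties by chrom, pos).
#' @export
filter_rare_small <- function(variants, gt, sample_id,
                              weights = evidence_weights()) {
  stopifnot(sample_id %in% colnames(gt))
  g <- gt[variants$variant_id, sample_id]
  carried <- !is.na(g) & g > 0L
  v <- variants[carried, , drop = FALSE]
  af0 <- function(nm) {
    if (nm %in% names(v)) ifelse(is.na(v[[nm]]), 0, v[[nm]]) else rep(0, nrow(v))
  }
  rare <- af0("af_1000g") < weights$af_rare_threshold &
    af0("af_gnomad") < weights$af_rare_threshold &
    af0("af_cohort") < weights$af_rare_threshold
  v <- v[rare, , drop = FALSE]
  v$rank_score <- ranking_score(v, weights)
  dplyr::arrange(v, dplyr::desc(.data$rank_score), .data$chrom, .data$pos)
}
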