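mk_variants <- function() {
  tibble::tibble(
    variant_id = c("v_novel", "v_common", "v_rare_cohort", "v_splice_low",
                   "v_splice_high"),
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "T",
    af_1000g = c(NA, NA, NA, NA, 0.001),
    af_gnomad = c(NA, 0.05, NA, NA, 0.002),
    af_cohort = c(NA, NA, 0.0002, 0.001, 0.001),
    cadd_phred = c(NA, 30, 5, 1.25, 18.5),
    ag = c(NA, NA, NA, 0.02, 0.99),
    al = NA_real_, dg = NA_real_, dl = NA_real_)
}

mk_gt <- function(variants, carried) {
  gt <- matrix(0L, nrow(variants), 1, dimnames = list(variants$variant_id, "P1"))
  gt[carried, 1] <- 1L
  gt
}

test_that("AF is the only hard filter; absent AFs mean novel", {
  v <- mk_variants()
  gt <- mk_gt(v, v$variant_id)
  kept <- filter_rare_small(v, gt, "P1")
  # absent from every AF source -> kept; gnomAD 5% -> dropped
  expect_true("v_novel" %in% kept$variant_id)
  expect_false("v_common" %in% kept$variant_id)
  expect_true("v_rare_cohort" %in% kept$variant_id)
  # non-carried variants never appear
  gt2 <- mk_gt(v, "v_novel")
  expect_equal(filter_rare_small(v, gt2, "P1")$variant_id, "v_novel")
})

test_that("ranking score is weighted CADD plus max splice delta", {
  v <- mk_variants()
  expect_equal(ranking_score(v[v$variant_id == "v_splice_high", ]), 19.49)
  expect_equal(ranking_score(v[v$variant_id == "v_splice_low", ]), 1.27)
  expect_equal(ranking_score(v[v$variant_id == "v_novel", ]), 0)
  w <- evidence_weights(cadd_weight = 0, splice_max_delta_weight = 10)
  expect_equal(ranking_score(v[v$variant_id == "v_splice_high", ], w), 9.9)
})

test_that("a low evidence score never removes a variant", {
  v <- mk_variants()
  gt <- mk_gt(v, v$variant_id)
  base <- filter_rare_small(v, gt, "P1")
  # the low-scoring deep-intronic variant (AG 0.02, CADD 1.25) is retained
  expect_true("v_splice_low" %in% base$variant_id)
  for (w in list(evidence_weights(),
                 evidence_weights(cadd_weight = 100),
                 evidence_weights(cadd_weight = 0, splice_max_delta_weight = 0))) {
    expect_setequal(filter_rare_small(v, gt, "P1", w)$variant_id,
                    base$variant_id)
  }
})

test_that("increasing CADD or a splice delta never lowers a variant's rank", {
  set.seed(5)
  v <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:20), chrom = "chr1", pos = 1:20 * 10L,
    ref = "A", alt = "T", af_1000g = NA_real_, af_gnomad = NA_real_,
    af_cohort = NA_real_,
    cadd_phred = runif(20, 0, 30), ag = runif(20), al = NA_real_,
    dg = NA_real_, dl = NA_real_)
  gt <- mk_gt(v, v$variant_id)
  rank_of <- function(tbl, id) which(tbl$variant_id == id)
  before <- filter_rare_small(v, gt, "P1")
  for (id in sample(v$variant_id, 5)) {
    v2 <- v
    v2$cadd_phred[v2$variant_id == id] <- v2$cadd_phred[v2$variant_id == id] + 10
    expect_lte(rank_of(filter_rare_small(v2, gt, "P1"), id), rank_of(before, id))
    v3 <- v
    v3$ag[v3$variant_id == id] <- 1
    expect_lte(rank_of(filter_rare_small(v3, gt, "P1"), id), rank_of(before, id))
  }
})
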