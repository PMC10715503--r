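test_that("the gene window boundary is inclusive at exactly 1 kb", {
  gene <- tibble::tibble(chrom = "chr1", start = 50000L, end = 80000L)
  cl <- tibble::tibble(chrom = "chr1",
                       start = c(60000L, 47000L, 46999L, 81000L, 81001L),
                       end = c(61000L, 49000L, 48999L, 90000L, 90001L))
  expect_equal(sv_window_overlap(cl, gene),
               c(TRUE, TRUE, FALSE, TRUE, FALSE))
  # an SV on another chromosome never overlaps
  cl2 <- tibble::tibble(chrom = "chr2", start = 60000L, end = 61000L)
  expect_false(sv_window_overlap(cl2, gene))
})

test_that("diagnostic yield reproduces the published cohort percentages", {
  expect_equal(diagnostic_yield(10, 41), 24.4)
  expect_equal(diagnostic_yield(18, 41), 43.9)
  expect_equal(diagnostic_yield(0, 41), 0)
  expect_error(diagnostic_yield(1, 0), "n_total")
  expect_error(diagnostic_yield(5, 4), "n_solved")
})

test_that("carrier enrichment reproduces the published contrast", {
  e <- carrier_enrichment(15, 75000, 3, 11)
  expect_equal(e$pct_cohort, 0.02)
  expect_equal(e$pct_sub, 27.3)
  expect_equal(carrier_enrichment(15, 75000, 3, 15)$pct_sub, 20)
  z <- carrier_enrichment(0, 1000, 0, 10)
  expect_equal(c(z$pct_cohort, z$pct_sub), c(0, 0))
  expect_true(is.na(z$ratio))
  expect_error(carrier_enrichment(2, 100, 3, 10), "carriers_sub")
  expect_error(carrier_enrichment(5, 100, 3, 200), "n_sub")
})

test_that("cohort summary reproduces the published accounting", {
  cases <- read_case_manifest(fixture_path("cohort_cases_synthetic.tsv"))
  cs <- cohort_summary(cases)
  expect_equal(cs$n_recruited, 56)
  expect_equal(cs$n_excluded, 7)
  expect_equal(cs$n_no_first_hit_info, 8)
  expect_equal(cs$n_correctly_recruited, 41)
  expect_equal(cs$n_previously_solved, 10)
  expect_equal(cs$n_newly_solved, 8)
  expect_equal(cs$yield_before, 24.4)
  expect_equal(cs$yield_after, 43.9)
  newly <- cases[cases$solved == "newly_solved", ]
  expect_equal(sum(newly$referral_condition == "cystic fibrosis"), 4)
  expect_error(cohort_summary(cases[0, ]), "non-empty")
  # broom-style accessors
  expect_equal(glance(cs)$yield_after, 43.9)
  expect_true("yield_before" %in% tidy(cs)$statistic)
})

test_that("screen_case recovers every planted second hit at rank 1", {
  tc <- test_cohort()
  co <- tc$cohort
  sc <- screen_cohort(co$cases, co$genes, tc$clusters, co$variants, co$gt,
                      co$pedigree, co$depth)
  cand <- tidy(sc)
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    top <- cand[cand$case_id == tr$case_id & cand$rank == 1, ]
    expect_equal(nrow(top), 1, label = tr$case_id)
    expect_true(candidate_matches_truth(top, tr), label = tr$case_id)
    if (tr$true_path == "HOMOZYGOUS_IN_ROH") {
      expect_equal(top$zygosity_path, "HOMOZYGOUS_IN_ROH")
      expect_equal(top$phase, "NOT_APPLICABLE")
      expect_true(top$in_roh)
    } else {
      expect_equal(top$phase, "TRANS")
    }
  }
})

test_that("the mosaic parental deletion is annotated on the candidate", {
  tc <- test_cohort()
  co <- tc$cohort
  tr <- co$truth[co$truth$kind == "mosaic_parent_SV", ]
  case <- co$cases[co$cases$case_id == tr$case_id, ]
  cand <- screen_case(case, co$genes, tc$clusters, co$variants, co$gt,
                      co$pedigree, co$depth)
  top <- cand[1, ]
  expect_lt(abs(top$mosaic_father_pct - 44), 8)
  expect_match(top$notes, "father mosaicism")
})

test_that("the first-hit variant is never proposed as its own second hit", {
  tc <- test_cohort()
  co <- tc$cohort
  sc <- screen_cohort(co$cases, co$genes, tc$clusters, co$variants, co$gt,
                      co$pedigree, co$depth)
  cand <- tidy(sc)
  joined <- dplyr::inner_join(cand, co$cases[, c("case_id", "first_hit_id")],
                              by = "case_id")
  expect_false(any(joined$candidate_id == joined$first_hit_id, na.rm = TRUE))
  # unplanted cases, whose only window variant is their first hit, are empty
  unplanted <- setdiff(co$cases$case_id, co$truth$case_id)
  fp <- mean(unplanted %in% cand$case_id)
  expect_lte(fp, 0.1)
})

test_that("cis candidates are retained but ranked last", {
  genes <- tibble::tibble(gene_id = "G1", symbol = "G1", chrom = "chr1",
                          start = 1000L, end = 9000L, strand = "+",
                          exons = list(tibble::tibble(start = 1000L, end = 1100L)))
  v <- tibble::tibble(
    variant_id = c("fh", "cis_cand", "trans_cand"), chrom = "chr1",
    pos = c(1010L, 2000L, 3000L), ref = "A", alt = "T",
    af_1000g = NA_real_, af_gnomad = NA_real_, af_cohort = NA_real_,
    cadd_phred = c(25, 30, 2), ag = NA_real_, al = NA_real_, dg = NA_real_,
    dl = NA_real_)
  gt <- matrix(0L, 3, 3, dimnames = list(v$variant_id, c("P", "M", "F")))
  gt[, "P"] <- 1L
  gt["fh", "M"] <- 1L; gt["cis_cand", "M"] <- 1L; gt["trans_cand", "F"] <- 1L
  ped <- tibble::tibble(sample_id = c("P", "M", "F"), family_id = "FAM",
                        father_id = c("F", NA, NA), mother_id = c("M", NA, NA),
                        sex = c(1L, 2L, 1L), affected = c(2L, 1L, 1L))
  clusters <- cohort_frequency(cluster_sv_calls(random_calls(0)), 10)
  case <- list(case_id = "FAM", sample_id = "P", first_hit_gene = "G1",
               first_hit_kind = "small_variant", first_hit_id = "fh")
  cand <- screen_case(case, genes, clusters, v, gt, ped)
  expect_equal(nrow(cand), 2) # cis candidate kept, never silently dropped
  expect_equal(cand$candidate_id, c("trans_cand", "cis_cand"))
  expect_equal(cand$phase, c("TRANS", "CIS"))
  # despite the cis candidate's much higher evidence score
  expect_gt(cand$rank_score[2], cand$rank_score[1])
})

test_that("screening is deterministic and errors on an unknown gene", {
  tc <- test_cohort()
  co <- tc$cohort
  case <- co$cases[1, ]
  a <- screen_case(case, co$genes, tc$clusters, co$variants, co$gt,
                   co$pedigree, co$depth)
  b <- screen_case(case, co$genes, tc$clusters, co$variants, co$gt,
                   co$pedigree, co$depth)
  expect_identical(a, b)
  bad <- case
  bad$first_hit_gene <- "NOSUCHGENE"
  expect_error(screen_case(bad, co$genes, tc$clusters, co$variants, co$gt,
                           co$pedigree), "NOSUCHGENE")
})
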