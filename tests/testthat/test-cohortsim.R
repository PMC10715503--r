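small_cfg <- function(seed = 5, ...) {
  sim_config(n_families = 25, n_planted_cases = 4,
             planted_kinds = c("second_hit_SV", "second_hit_intronic_SNV",
                               "homozygous_in_ROH", "mosaic_parent_SV"),
             n_background_sv_clusters = 6, seed = seed, ...)
}

test_that("config validation rejects impossible plans", {
  expect_error(sim_config(n_families = 3, n_planted_cases = 10), "exceeds")
  expect_error(sim_config(planted_kinds = c("x"), n_planted_cases = 1),
               "unknown planted kind")
  expect_error(sim_config(planted_kinds = "second_hit_SV"), "length")
})

test_that("the same seed writes byte-identical cohorts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(small_cfg()), d1)
  write_cohort(simulate_cohort(small_cfg()), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed does not
  write_cohort(simulate_cohort(small_cfg(seed = 6)), d2)
  expect_false(identical(readLines(file.path(d1, "small_variants.vcf")),
                         readLines(file.path(d2, "small_variants.vcf"))))
})

test_that("breakpoint jitter is honest: zero sd is the identity, order repaired", {
  sv <- mk_call(start = 10000, end = 20000)
  set.seed(1)
  expect_equal(jitter_call(sv, 0)[, c("svtype", "chrom", "start", "end")],
               sv[, c("svtype", "chrom", "start", "end")])
  # a 2 bp interval under heavy jitter still comes back valid
  tiny <- mk_call(start = 100, end = 101)
  for (i in 1:200) {
    j <- jitter_call(tiny, 50)
    expect_true(j$start >= 1 && j$end >= j$start)
    expect_equal(j$svtype, "DEL")
  }
})

test_that("jittered caller pairs stay nearly identical to the true SV", {
  set.seed(19)
  sv <- mk_call(start = 100000, end = 109999) # 10 kb
  ro <- replicate(3000, {
    j <- jitter_call(sv, 20)
    reciprocal_overlap(j$chrom, j$start, j$end, sv$chrom, sv$start, sv$end)
  })
  expect_gte(mean(ro >= 0.98), 0.99)
})

test_that("non-planted trio genotypes are Mendelian-consistent", {
  co <- simulate_cohort(small_cfg())
  planted_fams <- unique(co$truth$case_id)
  fams <- setdiff(unique(co$pedigree$family_id), planted_fams)
  set.seed(2)
  idx <- sample(nrow(co$variants), 400)
  for (f in sample(fams, 5)) {
    p <- co$gt[idx, paste0(f, "_P")]
    m <- co$gt[idx, paste0(f, "_M")]
    fa <- co$gt[idx, paste0(f, "_F")]
    expect_true(all(mendelian_consistent(p, m, fa)))
  }
})

test_that("background clusters realise close to their configured frequency", {
  freqs <- c()
  for (seed in 1:3) {
    cfg <- sim_config(n_families = 150, n_planted_cases = 0,
                      planted_kinds = character(),
                      n_background_sv_clusters = 1,
                      background_freq_spectrum = 0.05, seed = seed)
    co <- simulate_cohort(cfg)
    cl <- cohort_frequency(cluster_sv_calls(co$sv_calls), nrow(co$pedigree))
    expect_equal(nrow(cl), 1) # jittered calls of one background SV aggregate
    freqs <- c(freqs, cl$cohort_frequency)
  }
  n <- 450
  sd3 <- 3 * sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(freqs - 0.05) <= sd3 + 1e-9))
  # a 5% cluster is never prioritised as rare
  expect_true(all(freqs >= 0.01))
})

test_that("planted pairs are genuinely in trans by construction", {
  co <- simulate_cohort(small_cfg())
  tr <- co$truth[co$truth$second_hit_type == "snv" &
                   co$truth$true_path == "COMPOUND_HET", ]
  for (i in seq_len(nrow(tr))) {
    fam <- tr$case_id[i]
    fh <- tr$first_hit_id[i]; sh <- tr$second_hit_id[i]
    o1 <- inherited_from(co$gt[fh, paste0(fam, "_P")],
                         co$gt[fh, paste0(fam, "_M")],
                         co$gt[fh, paste0(fam, "_F")])
    o2 <- inherited_from(co$gt[sh, paste0(fam, "_P")],
                         co$gt[sh, paste0(fam, "_M")],
                         co$gt[sh, paste0(fam, "_F")])
    expect_equal(phase_pair(o1, o2), "TRANS")
  }
})

test_that("the mosaic parent is genotyped het but depleted in depth", {
  co <- simulate_cohort(small_cfg())
  tr <- co$truth[co$truth$kind == "mosaic_parent_SV", ]
  fam <- tr$case_id[1]
  sv <- list(chrom = tr$second_chrom[1], start = tr$second_start[1],
             end = tr$second_end[1])
  # genotyped heterozygous by both callers
  calls <- dplyr::filter(co$sv_calls, sample_id == paste0(fam, "_F"),
                         chrom == sv$chrom, abs(start - sv$start) < 5000)
  expect_true(all(calls$genotype == "het"))
  est <- estimate_mosaic(co$depth, paste0(fam, "_F"), sv)
  expect_lt(abs(est$fraction_pct - 44), 8)
  est_p <- estimate_mosaic(co$depth, paste0(fam, "_P"), sv)
  expect_gt(est_p$fraction_pct, 90) # proband constitutively het
})
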