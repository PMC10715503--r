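test_that("calls_match applies type, reciprocal-overlap and insertion rules", {
  a <- mk_call(start = 1000, end = 11000)
  b <- mk_call(start = 1500, end = 11200, caller = "callerB") # RO ~ 0.88
  expect_true(calls_match(a, b))
  expect_false(calls_match(a, mk_call(svtype = "DUP", start = 1000, end = 11000)))
  # insertions: breakpoint proximity + length similarity (1591 vs 1600)
  i1 <- mk_call(svtype = "INS", start = 5000, end = 5000, ins_length = 1591)
  i2 <- mk_call(svtype = "INS", start = 5010, end = 5010, ins_length = 1600)
  expect_true(calls_match(i1, i2))
  expect_false(calls_match(i1, mk_call(svtype = "INS", start = 5200, end = 5200,
                                       ins_length = 1591)))
  # mixed INS / non-INS is FALSE, never an error
  expect_false(calls_match(i1, a))
  # threshold is configurable
  c1 <- mk_call(start = 1001, end = 2000)
  c2 <- mk_call(start = 1101, end = 2100) # RO = 0.9
  expect_true(calls_match(c1, c2, sv_match_params(ro_threshold = 0.9)))
  expect_false(calls_match(c1, c2, sv_match_params(ro_threshold = 0.95)))
})

test_that("two callers' jittered reports of one SV form a single cluster", {
  calls <- dplyr::bind_rows(
    mk_call(caller = "callerA", start = 20000, end = 30000),
    mk_call(caller = "callerB", start = 20018, end = 29980))
  cl <- cluster_sv_calls(calls)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_carriers, 1)
  expect_equal(cl$carriers[[1]], "S1")
  # representative interval is the per-coordinate lower median
  expect_equal(cl$start, 20000L)
  expect_equal(cl$end, 29980L)
})

test_that("clustering of empty input is empty", {
  expect_equal(nrow(cluster_sv_calls(random_calls(0))), 0)
})

test_that("clustering partitions calls and matches the brute-force oracle", {
  set.seed(77)
  for (rep in 1:100) {
    calls <- random_calls(sample(2:50, 1))
    cl <- cluster_sv_calls(calls)
    members <- purrr::list_rbind(cl$members)
    # partition: every call in exactly one cluster
    expect_equal(nrow(members), nrow(calls))
    groups <- rep(seq_len(nrow(cl)), vapply(cl$members, nrow, integer(1)))
    oracle <- brute_force_components(calls)
    expect_identical(clustering_signature(groups, members),
                     clustering_signature(oracle, calls))
    # carriers are the union of member sample ids
    for (k in seq_len(nrow(cl))) {
      expect_setequal(cl$carriers[[k]], unique(cl$members[[k]]$sample_id))
    }
  }
})

test_that("raising the overlap threshold never merges clusters", {
  set.seed(88)
  for (rep in 1:20) {
    calls <- random_calls(30)
    counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99), function(thr) {
      nrow(cluster_sv_calls(calls, sv_match_params(ro_threshold = thr)))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("cohort frequency counts carriers per participant", {
  cl <- tibble::tibble(cluster_id = "SVC00001", n_carriers = 15L)
  expect_equal(cohort_frequency(cl, 75000)$cohort_frequency, 0.0002)
  expect_equal(cohort_frequency(dplyr::mutate(cl, n_carriers = 1L),
                                100)$cohort_frequency, 0.01)
  expect_error(cohort_frequency(cl, 0), "positive")
  expect_error(cohort_frequency(cl, 10), "carrier count")
})

test_that("rarity uses a strict < 1% cut", {
  cl <- tibble::tibble(cluster_id = c("a", "b", "c"),
                       cohort_frequency = c(0.0099, 0.01, 1 / 75000))
  kept <- rare_clusters(cl)
  expect_equal(kept$cluster_id, c("a", "c"))
  # 750 carriers out of 75,000 sits exactly at 1% and is not rare
  at_cut <- cohort_frequency(tibble::tibble(cluster_id = "d",
                                            n_carriers = 750L), 75000)
  expect_equal(nrow(rare_clusters(at_cut)), 0)
})
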