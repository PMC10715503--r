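make_sites <- function(pos, het) {
  tibble::tibble(pos = as.integer(pos), gt = ifelse(het, 1L, 2L))
}

test_that("an all-heterozygous sample yields no ROH", {
  sites <- make_sites(seq(1e6, 50e6, by = 5e4), het = TRUE)
  expect_equal(nrow(detect_roh(sites)), 0)
})

test_that("a planted homozygous block is recovered almost entirely", {
  set.seed(21)
  block <- c(100e6, 120e6) # 20 Mb
  sites <- simulate_roh_sites(block[1], block[2], het_error = 0.005)
  regions <- detect_roh(sites)
  expect_equal(nrow(regions), 1)
  covered <- min(regions$end, block[2]) - max(regions$start, block[1]) + 1
  expect_gte(covered / (block[2] - block[1] + 1), 0.95)
})

test_that("two homozygous blocks split by a het-dense gap give two regions", {
  pos <- seq(25e3, 20e6, by = 25e3)
  in_b1 <- pos >= 2e6 & pos <= 7e6
  in_b2 <- pos >= 9e6 & pos <= 14e6
  het <- !(in_b1 | in_b2) # gap and flanks fully heterozygous
  regions <- detect_roh(make_sites(pos, het))
  expect_equal(nrow(regions), 2)
  expect_true(regions$start[2] > regions$end[1])
})

test_that("unsorted input is rejected", {
  s <- make_sites(c(100, 50, 200), het = FALSE)
  expect_error(detect_roh(s), "sorted")
})

test_that("reported regions satisfy their own invariants on random inputs", {
  set.seed(31)
  for (rep in 1:10) {
    pos <- seq(5e4, 40e6, by = 5e4)
    het <- runif(length(pos)) < runif(1, 0.05, 0.6)
    regions <- detect_roh(make_sites(pos, het))
    if (nrow(regions) == 0) next
    expect_true(all(regions$end - regions$start + 1 >= 2e6))
    expect_true(all(regions$n_sites >= 100))
    expect_true(all(regions$n_het / regions$n_sites <= 0.05))
  }
})

test_that("raising min_length never adds regions", {
  set.seed(41)
  pos <- seq(5e4, 60e6, by = 5e4)
  het <- runif(length(pos)) < 0.25
  het[pos >= 10e6 & pos <= 16e6] <- runif(sum(pos >= 10e6 & pos <= 16e6)) < 0.004
  counts <- vapply(c(1, 2, 4, 8, 16),
                   function(ml) nrow(detect_roh(make_sites(pos, het),
                                                min_length_mb = ml)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("containing_roh requires full containment and prefers the longest", {
  regions <- tibble::tibble(chrom = c("chr1", "chr1"),
                            start = c(10e6, 5e6), end = c(30e6, 45e6),
                            n_sites = c(400L, 800L), n_het = c(1L, 2L))
  inside <- list(chrom = "chr1", start = 12e6, end = 12.1e6)
  hit <- containing_roh(regions, inside)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$end, 45e6) # the longer of the two containing regions
  straddle <- list(chrom = "chr1", start = 29e6, end = 46e6)
  expect_equal(nrow(containing_roh(regions, straddle)), 0)
  expect_equal(nrow(containing_roh(regions[0, ], inside)), 0)
})
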