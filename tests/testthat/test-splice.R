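test_that("acceptor gain retains |offset| - 1 intronic nucleotides", {
  expect_equal(acceptor_gain_retention(-26), 25) # the c.3140-26A>G case
  expect_equal(acceptor_gain_retention(-3), 2)
  expect_equal(acceptor_gain_retention(-101), 100)
  expect_error(acceptor_gain_retention(-2), "canonical")
  expect_error(acceptor_gain_retention(5), "canonical")
})

test_that("pseudoexon length is inclusive", {
  g <- 5000L
  expect_equal(pseudoexon_length(g, g + 124L), 125) # 125 bp pseudoexon
  expect_equal(pseudoexon_length(g, g), 1)
  expect_equal(pseudoexon_length(g, g + 71L), 72)
  expect_false(frameshift(pseudoexon_length(g, g + 71L))) # 72 nt is in frame
  expect_error(pseudoexon_length(10, 9))
})

test_that("exon skip consequence reports removed length and frame status", {
  cons <- exon_skip_consequence(11023, 11095) # published skipped exon
  expect_equal(cons$removed_nt, 73)
  expect_true(cons$frameshift)
  expect_equal(exon_skip_consequence(100, 171)$removed_nt, 72)
  expect_false(exon_skip_consequence(100, 171)$frameshift)
  expect_true(exon_skip_consequence(5, 5)$frameshift)
  expect_error(exon_skip_consequence(10, 5))
})

test_that("frameshift is the mod-3 rule", {
  expect_true(frameshift(125))
  expect_true(frameshift(25))
  expect_false(frameshift(3))
  expect_error(frameshift(-1))
})

test_that("HGVS parser handles the supported patterns (incl. en-dash)", {
  p <- parse_splice_hgvs("c.3140-26A>G")
  expect_equal(p$kind, "intronic_sub")
  expect_equal(p$offset, -26L)
  # text copied from publications often carries an en-dash
  p2 <- parse_splice_hgvs("c.3140–26A>G")
  expect_equal(p2$offset, -26L)
  d <- parse_splice_hgvs("c.11023_11095del")
  expect_equal(c(d$c_start, d$c_end), c(11023L, 11095L))
  i <- parse_splice_hgvs("c.2848_2849ins1591")
  expect_equal(i$ins_length, 1591L)
  expect_error(parse_splice_hgvs("c.76A>T"), "unsupported")
  expect_error(parse_splice_hgvs("p.(Phe508del)"), "unsupported")
})

test_that("splice_consequence arithmetic matches the published variants", {
  res <- splice_consequence(parse_splice_hgvs(
    c("c.3140-26A>G", "c.11023_11095del", "c.2848_2849ins1591")))
  expect_equal(res$altered_nt, c(25L, 73L, 1591L))
  expect_equal(res$frameshift, c(TRUE, TRUE, TRUE))
})

test_that("frameshift flag always equals mod-3 of the length output", {
  set.seed(3)
  offs <- -sample(3:500, 50)
  expect_equal(frameshift(acceptor_gain_retention(offs)),
               (abs(offs) - 1) %% 3 != 0)
  s <- sample(1:10000, 50); e <- s + sample(0:400, 50, replace = TRUE)
  cons <- exon_skip_consequence(s, e)
  expect_equal(cons$frameshift, cons$removed_nt %% 3 != 0)
})

test_that("retained length strictly increases with |offset|", {
  r <- acceptor_gain_retention(seq(-3, -200))
  expect_true(all(diff(r) > 0))
})
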