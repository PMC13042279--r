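test_that("YCAY counting is a sliding window with overlaps", {
  expect_equal(count_ycay("AAAA"), 0L)
  expect_equal(count_ycay("TCACCCAT"), 2L)       # TCAC, CCAT
  expect_equal(count_ycay("TCATCAT"), 2L)        # overlap at one base
  expect_equal(count_ycay("ucacu"), 1L)          # U mapped to T
  expect_equal(count_ycay("GG"), 0L)
  err <- tryCatch(count_ycay("ACGNT"), error = conditionMessage)
  expect_match(err, "offset 3")
})

test_that("counts equal the exhaustive 4-mer window oracle on random strings", {
  withr::with_seed(101, {
    for (i in 1:1000) {
      s <- paste(sample(c("A", "C", "G", "T"), sample(4:60, 1), TRUE),
                 collapse = "")
      expect_identical(count_ycay(s), oracle_ycay(s))
    }
  })
})

test_that("the expected density on uniform sequence is (L-3)/64", {
  withr::with_seed(7, {
    L <- 1e6
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  })
  expect_equal(count_ycay(s) / ((L - 3) * 4 / 256), 1, tolerance = 0.05)
})

test_that("profiles partition counts by exon and flanking intron", {
  ## synthetic 2-exon gene with planted sites: 3 in exon 1, 5 in exon 2
  e1 <- plant_ycay_str(180, 3); e2 <- plant_ycay_str(200, 5)
  intron <- plant_ycay_str(300, 4)
  g <- structure(stats::setNames(paste0(e1, intron, e2), "c"),
                 class = "toy_genome")
  gm <- structure(list(gene_id = "g2", contig = "c", strand = "+",
                       exons = cbind(start = c(0L, 480L),
                                     end = c(180L, 680L)),
                       focus_exon = 2L, alt_offset = NA_integer_,
                       circ_exons = integer(0)), class = "gene_model")
  p <- profile_transcript(gm, g)
  expect_equal(p$exon_counts, c(3L, 5L))
  expect_equal(p$exonic_total, 8L)
  expect_equal(p$intron_upstream, 4L)
  expect_true(is.na(p$intron_downstream))        # no intron after exon 2
  ## all-A transcript has zero everywhere
  gA <- structure(stats::setNames(strrep("A", 700), "c"),
                  class = "toy_genome")
  pA <- profile_transcript(gm, gA)
  expect_equal(sum(pA$exon_counts), 0L)
  expect_error(profile_transcript(gm, g, focus_exon = 9), "focus exon")
})

test_that("scanning is transcript-oriented, not reverse-complement symmetric", {
  ## same transcript on + and - strands must give identical counts,
  ## while scanning the raw genomic strand of the - gene differs
  e1 <- plant_ycay_str(150, 4); e2 <- plant_ycay_str(150, 2)
  intron <- plant_ycay_str(200, 1)
  tx_plus <- paste0(e1, intron, e2)
  g <- structure(stats::setNames(tx_plus, "c"), class = "toy_genome")
  grc <- structure(stats::setNames(revcomp(tx_plus), "c"),
                   class = "toy_genome")
  gm_plus <- structure(list(gene_id = "gp", contig = "c", strand = "+",
                            exons = cbind(start = c(0L, 350L),
                                          end = c(150L, 500L)),
                            focus_exon = 1L, alt_offset = NA_integer_,
                            circ_exons = integer(0)), class = "gene_model")
  gm_minus <- gm_plus; gm_minus$strand <- "-"; gm_minus$gene_id <- "gm"
  gm_minus$focus_exon <- 2L        # same transcript exon, flipped order
  pp <- profile_transcript(gm_plus, g)
  pm <- profile_transcript(gm_minus, grc)
  expect_equal(pm$exon_counts, pp$exon_counts)
  expect_equal(pm$exonic_total, pp$exonic_total)
  ## YCAY is not an RC palindrome: the raw minus-strand scan differs
  expect_false(isTRUE(all.equal(count_ycay(revcomp(e1)), count_ycay(e1))))
})

test_that("density categories use the low/intermediate/enriched bins", {
  expect_equal(categorize_ycay(c(0, 19, 20, 59, 60, 61, 150)),
               c("low", "low", "intermediate", "intermediate",
                 "enriched", "enriched", "enriched"))
})

test_that("set comparison reports proportions, odds ratio and exact-test P", {
  withr::with_seed(11, x <- rpois(40, 30))
  same <- compare_sets(x, x)
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p_value, 1)
  ## the 48% vs 14% mix at n = 195 / 200
  sig <- c(rep(25, 94), rep(5, 101))
  ctl <- c(rep(25, 28), rep(5, 172))
  cs <- compare_sets(sig, ctl, cut = 20)
  expect_equal(cs$table["atOrAbove", "significant"], 94)
  expect_equal(cs$prop_significant, 94 / 195, tolerance = 1e-12)
  expect_equal(cs$prop_control, 28 / 200, tolerance = 1e-12)
  expect_lt(cs$p_value, 1e-10)
  ## hypergeometric oracle for the one-sided tail bounds the two-sided P
  tail_p <- sum(dhyper(94:122, 122, 273, 195))
  expect_lte(tail_p, cs$p_value + 1e-12)
  ## complete separation
  sep <- compare_sets(rep(30, 10), rep(2, 10))
  expect_equal(sep$prop_significant, 1)
  expect_equal(sep$prop_control, 0)
  expect_error(compare_sets(numeric(0), ctl), "non-empty")
})
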