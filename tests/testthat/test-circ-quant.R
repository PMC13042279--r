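toy_genome <- function(seq, name = "chr") {
  structure(stats::setNames(seq, name), class = "toy_genome")
}

test_that("scaffolds are 200 nt with the seam centred, all circle sizes", {
  withr::with_seed(1, {
    g <- toy_genome(paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                          collapse = ""))
  })
  ## long circle (>= 200): last 100 + first 100
  loc <- list(circ_id = "c1", contig = "chr", start = 100L, end = 400L,
              strand = "+")
  sc <- build_scaffold(loc, g)
  expect_equal(nchar(sc$seq), 200L)
  expect_equal(sc$seam, 100L)
  circ <- substr(g[[1]], 101, 400)
  expect_equal(sc$seq, paste0(substr(circ, 201, 300), substr(circ, 1, 100)))

  ## exactly 200: a rotation of the full circle
  loc2 <- list(circ_id = "c2", contig = "chr", start = 100L, end = 300L,
               strand = "+")
  sc2 <- build_scaffold(loc2, g)
  circ2 <- substr(g[[1]], 101, 300)
  expect_equal(sc2$seq, paste0(substr(circ2, 101, 200), substr(circ2, 1, 100)))

  ## 60-mer: tiled circularly; verify against a hand-built string
  loc3 <- list(circ_id = "c3", contig = "chr", start = 100L, end = 160L,
               strand = "+")
  sc3 <- build_scaffold(loc3, g)
  circ3 <- substr(g[[1]], 101, 160)
  tiled <- strrep(circ3, 4)
  hand <- paste0(substr(tiled, nchar(tiled) - 99, nchar(tiled)),
                 substr(tiled, 1, 100))
  expect_equal(sc3$seq, hand)

  ## minus strand: reverse complement orientation
  loc4 <- list(circ_id = "c4", contig = "chr", start = 100L, end = 400L,
               strand = "-")
  sc4 <- build_scaffold(loc4, g)
  rcirc <- revcomp(circ)
  expect_equal(sc4$seq, paste0(substr(rcirc, 201, 300), substr(rcirc, 1, 100)))

  expect_error(build_scaffold(list(circ_id = "x", contig = "chr",
                                   start = 900L, end = 1100L, strand = "+"),
                              g),
               "fit")
})

test_that("the split-read caller recovers simulated loci exactly", {
  s <- make_test_sim(seed = 31)
  loci <- call_bsj(s$sim$samples, s$fx$genome)
  key_called <- paste(loci$contig, loci$start, loci$end, loci$strand)
  key_true <- paste(s$fx$circs$contig, s$fx$circs$start, s$fx$circs$end,
                    s$fx$circs$strand)
  ## every simulated circle with adequate support is recovered exactly,
  ## including the two acceptor isoforms 6 nt apart
  pooled <- rowSums(s$sim$truth$circ_unique)
  expect_true(all(key_true[pooled >= 5] %in% key_called))
  expect_true(all(key_called %in% key_true))
  crh <- s$fx$circs[s$fx$circs$gene_id == "crh1L", ]
  hit <- loci[loci$end == crh$end[1], ]
  expect_equal(nrow(hit), 2L)
  expect_equal(sort(hit$start), sort(crh$start))
})

test_that("linear reads produce no back-splice calls", {
  fx <- make_fixture(fixture_config(seed = 2))
  g <- fx$genome[[1]]
  linear <- vapply(seq(1, 3000, by = 37),
                   function(i) substr(g, i, i + 149), character(1))
  out <- call_bsj(linear, fx$genome)
  expect_equal(nrow(out), 0L)
})

test_that("junction counting is exact, deduplicated and strand-symmetric", {
  s <- make_test_sim(seed = 13)
  scafs <- lapply(seq_len(nrow(s$fx$circs)), function(i)
    build_scaffold(s$fx$circs[i, ], s$fx$genome))
  cl <- count_junction_reads(scafs, s$sim$samples)
  m <- junction_count_matrix(cl, "unique")
  tr <- s$sim$truth$circ_unique
  expect_equal(m[rownames(tr), colnames(tr)], tr, ignore_attr = TRUE)
  mr <- junction_count_matrix(cl, "raw")
  expect_equal(mr[rownames(tr), colnames(tr)], s$sim$truth$circ_raw,
               ignore_attr = TRUE)
  expect_true(all(m <= mr))

  ## reverse-complementing every read leaves unique counts unchanged
  one <- s$sim$samples$WT_1
  flipped <- data.frame(id = one$id, r1 = revcomp(one$r1),
                        r2 = revcomp(one$r2), stringsAsFactors = FALSE)
  c1 <- count_junction_reads(scafs, list(WT_1 = one))
  c2 <- count_junction_reads(scafs, list(WT_1 = flipped))
  expect_equal(c1$unique, c2$unique)

  ## empty input
  c0 <- count_junction_reads(scafs, data.frame(r1 = character(0),
                                               r2 = character(0)))
  expect_true(all(c0$raw == 0L) && all(c0$unique == 0L))
})

test_that("byte-identical duplicate pairs collapse to the unique count", {
  fx <- make_fixture(fixture_config(seed = 5))
  sc <- build_scaffold(fx$circs[fx$circs$circ_id == "circ_cirA_1", ],
                       fx$genome)
  ## 30 read pairs: 21 distinct placements, one emitted 10 times
  p1 <- c(0:20, rep(0L, 9)); p2 <- c(20:0, rep(20L, 9))
  r1 <- substr(rep(sc$seq, 30), p1 + 1, p1 + 150)
  r2 <- revcomp(substr(rep(sc$seq, 30), p2 + 1, p2 + 150))
  reads <- data.frame(r1 = r1, r2 = r2, stringsAsFactors = FALSE)
  out <- count_junction_reads(list(sc), reads)
  expect_equal(out$raw, 30L)
  expect_equal(out$unique, oracle_collapse(paste(p1, p2)))
  expect_equal(out$unique, 21L)
})

test_that("the junction-read filter applies the pooled < threshold rule", {
  m <- matrix(c(2, 3, 5, 7, 40, 60), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  f <- filter_circ(m, 12)
  expect_equal(rownames(f), c("b", "c"))         # pooled {5, 12, 100}
  expect_equal(attr(f, "removed"), "a")
  ## boundary: pooled 11 removed, pooled 12 kept
  m2 <- matrix(c(5, 6, 6, 6), nrow = 2, byrow = TRUE,
               dimnames = list(c("just_below", "at"), c("s1", "s2")))
  expect_equal(rownames(filter_circ(m2, 12)), "at")
  ## row order preserved, empty input passes through
  expect_equal(nrow(filter_circ(m[0, , drop = FALSE], 12)), 0L)
  expect_error(filter_circ(m, -1), "must be")
})
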