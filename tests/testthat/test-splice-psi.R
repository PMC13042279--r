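grp10 <- c(rep("WT", 5), rep("nova1", 5))

test_that("PSI arithmetic follows the length-normalised definition", {
  expect_equal(compute_psi(0, 50), 0)
  expect_equal(compute_psi(50, 0), 1)
  expect_equal(compute_psi(80, 20, l_I = 2, l_S = 1), 40 / 60)
  ## length-symmetric case reduces to I / (I + S)
  expect_equal(compute_psi(30, 10, 7, 7), 30 / 40)
  ## scale invariance
  expect_equal(compute_psi(8, 2, 2, 1), compute_psi(800, 200, 2, 1))
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(1, 1, l_I = 0), "effective lengths")
})

test_that("effective lengths count distinct junction read positions", {
  fx <- make_fixture(fixture_config(seed = 1))
  ll <- effective_lengths(fx$events$A3SS_crh1L, read_len = 150, overhang = 8)
  expect_equal(unname(ll), c(135, 135))          # 150 - 2*8 + 1 per junction
  ll2 <- effective_lengths(fx$events$SE_seG, 150, 8)
  expect_equal(unname(ll2), c(270, 135))         # two inclusion junctions
  ## jcec credits the retained intron body
  ll3 <- effective_lengths(fx$events$RI_riG, 150, 8, mode = "jcec")
  expect_equal(unname(ll3["l_I"]), 2 * 135 + (300 - 150 + 1))
  expect_error(effective_lengths(fx$events$SE_seG, 10, 8), "overhang")
})

test_that("event read counting assigns forms exactly on simulated data", {
  s <- make_test_sim(seed = 17)
  tr <- s$sim$truth$events
  for (eid in c("A3SS_crh1L", "SE_seG", "RI_riG")) {
    got <- count_event_reads(s$fx$events[[eid]],
                             s$sim$samples[c("WT_1", "nova1_1")],
                             s$fx$genome)
    want <- tr[tr$event_id == eid & tr$sample %in% c("WT_1", "nova1_1"), ]
    expect_equal(got$I, want$I, info = eid)
    expect_equal(got$S, want$S, info = eid)
  }
})

test_that("A3'SS reads with a seam inside the 6-nt window go to the long form", {
  fx <- make_fixture(fixture_config(seed = 2))
  ev <- fx$events$A3SS_crh1L
  es <- event_scaffolds(ev, fx$genome, flank = 150)
  long_sc <- es$inclusion[[1]]$seq
  ## reads whose right-of-seam part starts inside the 6 alt nt (overhang
  ## 8 forces them past the short acceptor into shared sequence)
  starts <- 136:142                       # right overhang 8..14 nt
  reads <- data.frame(r1 = substr(rep(long_sc, length(starts)),
                                  starts + 1, starts + 150),
                      r2 = revcomp(substr(rep(long_sc, length(starts)),
                                          1, 150)),
                      stringsAsFactors = FALSE)
  got <- count_event_reads(ev, reads, fx$genome)
  expect_equal(got$I, length(starts))
  expect_equal(got$S, 0L)
})

test_that("reads only from the inclusion isoform give S = 0", {
  fx <- make_fixture(fixture_config(seed = 2))
  ev <- fx$events$SE_seG
  es <- event_scaffolds(ev, fx$genome, flank = 150)
  r1 <- unlist(lapply(es$inclusion, function(sc)
    substr(rep(sc$seq, 10), 41:50, 190:199)))
  reads <- data.frame(r1 = r1, r2 = revcomp(r1), stringsAsFactors = FALSE)
  got <- count_event_reads(ev, reads, fx$genome)
  expect_equal(got$S, 0L)
  expect_equal(got$I, 20L)
})

test_that("the beta-binomial LRT is symmetric and reduces to binomial at rho 0", {
  withr::with_seed(41, {
    n <- rnbinom(10, mu = 150, size = 20)
    I <- rbinom(10, n, c(rep(0.7, 5), rep(0.45, 5)))
  })
  t1 <- test_event(I, n - I, grp10, ref_group = "WT")
  t2 <- test_event(I, n - I, grp10, ref_group = "nova1")
  expect_equal(t1$delta_psi, -t2$delta_psi)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-9)
  expect_gt(t1$delta_psi, 0)                     # WT-minus-mutant orientation
  ## zero-overdispersion fit equals the closed-form binomial LRT
  t0 <- test_event(I, n - I, grp10, rho = 0)
  expect_equal(t0$lrt, oracle_binom_lrt(I, n, grp10), tolerance = 1e-6)
  ## identical groups: no signal
  tn <- test_event(rep(c(40L, 41L), 5), rep(c(60L, 59L), 5), grp10)
  expect_lt(abs(tn$delta_psi), 0.02)
  expect_gt(tn$p_value, 0.3)
  ## degenerate all-inclusion data
  td <- test_event(rep(10L, 10), rep(0L, 10), grp10)
  expect_equal(td$p_value, 1)
  expect_error(test_event(1:2, 2:1, c("WT", "nova1")), "replicates")
})

test_that("event tables and the significance filter follow the thresholds", {
  s <- make_test_sim(seed = 23)
  ec <- do.call(rbind, lapply(names(s$fx$events), function(e)
    s$sim$truth$events[s$sim$truth$events$event_id == e,
                       c("event_id", "sample", "I", "S")]))
  psi <- psi_test_table(ec, s$sim$truth$genotype, events = s$fx$events)
  expect_setequal(psi$event_id, names(s$fx$events))
  expect_true(all(psi$IncLevelDifference >= -1 & psi$IncLevelDifference <= 1))
  expect_true(all(psi$FDR >= 0 & psi$FDR <= 1))
  ## the two true effects are recovered with the WT-minus-mutant sign
  expect_gt(psi$IncLevelDifference[psi$event_id == "A3SS_crh1L"], 0.2)
  expect_gt(psi$IncLevelDifference[psi$event_id == "SE_seG"], 0.15)

  flt <- filter_events(psi)
  expect_true(all(flt$significant$FDR <= 0.05))
  expect_true(all(abs(flt$significant$IncLevelDifference) >= 0.2))
  expect_equal(sum(flt$summary$n), nrow(flt$significant))

  ## boundary rule on a constructed table: FDR 0.04 with |dPSI| 0.19 is out
  tab <- data.frame(event_id = paste0("e", 1:5), type = "SE",
                    gene_id = paste0("g", 1:5),
                    IncLevelDifference = c(0.19, 0.25, -0.3, 0.5, 0.21),
                    PValue = c(0.001, 0.001, 0.001, 0.5, 0.001))
  tab$FDR <- c(0.04, 0.01, 0.02, 0.6, 0.03)
  out <- filter_events(tab)
  expect_setequal(out$significant$event_id, c("e2", "e3", "e5"))
  empty <- filter_events(tab[0, , drop = FALSE])
  expect_equal(nrow(empty$significant), 0L)
})
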