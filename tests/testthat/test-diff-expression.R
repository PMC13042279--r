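null_matrix <- function(G, mu = 100, phi = 0.05, n_per = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(G * 2 * n_per, mu = mu, size = 1 / phi), G, 2 * n_per)
    dimnames(m) <- list(paste0("f", seq_len(G)),
                        paste0(rep(c("WT", "mut"), each = n_per), "_",
                               rep(seq_len(n_per), 2)))
    m
  })
}
gt10 <- c(rep("WT", 5), rep("mut", 5))

test_that("BH adjustment matches the textbook step-up and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(3, p <- runif(50))
  expect_equal(bh_adjust(p), oracle_bh(p))
  ## invariant to permutation of the input order
  o <- sample(seq_along(p))
  expect_equal(bh_adjust(p[o])[order(o)], bh_adjust(p))
  ## monotone nondecreasing in sorted-p order
  expect_true(all(diff(bh_adjust(p)[order(p)]) >= 0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, -0.1)), "0, 1")
})

test_that("TMM-style factors behave on constructed matrices", {
  m <- null_matrix(200, seed = 11)
  same <- cbind(a = m[, 1], b = m[, 1], c = m[, 1])
  f <- normalize_tmm(same)
  expect_equal(unname(f$factors), rep(1, 3), tolerance = 1e-12)
  ## one column exactly doubled: factor ~ 1, effective size ~ 2x
  doubled <- cbind(a = m[, 1], b = m[, 2], c = 2L * m[, 1])
  fd <- normalize_tmm(doubled)
  expect_equal(unname(fd$factors["c"]), 1, tolerance = 0.02)
  expect_equal(unname(fd$effective["c"] / fd$effective["a"]), 2,
               tolerance = 0.05)
  ## geometric mean of factors is 1 for any input
  expect_equal(exp(mean(log(normalize_tmm(m)$factors))), 1, tolerance = 1e-12)
  bad <- cbind(a = m[, 1], z = 0L * m[, 1])
  expect_error(normalize_tmm(bad), "z")
})

test_that("the NB QL test is symmetric, scale-stable and null-centred", {
  m <- null_matrix(60, seed = 21)
  r1 <- fit_nb_test(m, gt10, ref_level = "WT")
  ## swapping genotype labels negates log2FC and keeps P
  r2 <- fit_nb_test(m, gt10, ref_level = "mut")
  expect_equal(r1$log2FC, -r2$log2FC, tolerance = 1e-6)
  expect_equal(r1$PValue, r2$PValue, tolerance = 1e-6)
  ## scaling counts and library sizes by a common factor keeps log2FC
  r3 <- fit_nb_test(4L * m, gt10, ref_level = "WT",
                    effective_lib = 4 * colSums(m))
  r1b <- fit_nb_test(m, gt10, ref_level = "WT", effective_lib = colSums(m))
  expect_equal(r3$log2FC, r1b$log2FC, tolerance = 0.05)
  ## the alternative sign-orientation flag flips log2FC
  r4 <- fit_nb_test(m, gt10, ref_level = "WT", paper_sign = TRUE)
  expect_equal(r4$log2FC, -r1$log2FC)
  ## constant equal groups: log2FC 0, P near 1
  flat <- matrix(50L, 8, 10,
                 dimnames = list(paste0("f", 1:8), colnames(m)))
  rf <- fit_nb_test(flat, gt10, effective_lib = rep(1e6, 10))
  expect_equal(rf$log2FC, rep(0, 8), tolerance = 1e-8)
  expect_true(all(rf$PValue > 0.99))
  ## all-zero features are excluded and tallied
  mz <- rbind(m, zero = 0L)
  rz <- fit_nb_test(mz, gt10)
  expect_equal(attr(rz, "excluded"), "zero")
  expect_equal(nrow(rz), nrow(m))
})

test_that("estimates agree with the established QL implementation", {
  skip_if_not_installed("edgeR")
  withr::with_seed(31, {
    G <- 120
    mu <- exp(runif(G, log(20), log(400)))
    fc <- rep(c(1, 2, 0.5), length.out = G)
    m <- t(vapply(seq_len(G), function(g)
      rnbinom(10, mu = mu[g] * c(rep(1, 5), rep(fc[g], 5)), size = 20),
      numeric(10)))
    dimnames(m) <- list(paste0("f", 1:G), names(gt10))
  })
  mine <- fit_nb_test(m, gt10, ref_level = "WT",
                      effective_lib = colSums(m))
  y <- edgeR::DGEList(m, group = factor(gt10, levels = c("WT", "mut")))
  y$samples$norm.factors <- 1
  design <- model.matrix(~group, y$samples)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  qlf <- edgeR::glmQLFTest(fit)
  ed <- edgeR::topTags(qlf, n = Inf, sort.by = "none")$table
  expect_gt(cor(mine$log2FC, ed$logFC), 0.99)
  expect_lt(median(abs(mine$log2FC - ed$logFC)), 0.05)
  ## significance ranking agrees closely
  expect_gt(cor(log(mine$PValue), log(ed$PValue), method = "spearman"), 0.95)
})

test_that("DE classification applies the fold/significance rule", {
  r <- data.frame(feature = c("a", "b", "c", "d"),
                  log2FC = c(0.8, -0.6, -0.9, 0),
                  PValue = c(0.01, 0.2, 0.001, 1e-9),
                  FDR = c(0.02, 0.3, 0.002, 1e-8))
  cl <- classify_de(r)
  expect_equal(cl$call, c("up", "ns", "down", "ns"))
  ## log2FC 0 is ns regardless of P; boundary 0.5 is not strict-greater
  r2 <- data.frame(feature = "e", log2FC = 0.5, PValue = 0.001, FDR = 0.001)
  expect_equal(classify_de(r2)$call, "ns")
  expect_error(classify_de(r, lfc_threshold = 0), "positive")
  ## fdr gating mode
  r3 <- data.frame(feature = "f", log2FC = 1, PValue = 0.01, FDR = 0.2)
  expect_equal(classify_de(r3, use = "fdr")$call, "ns")
  expect_equal(classify_de(r3, use = "p")$call, "up")
})

test_that("the minimum detectable fold change is ~1.4 at the 0.5 threshold", {
  expect_equal(min_fold_change(0.5), 2^0.5)
  expect_equal(min_fold_change(0.5), 1.41, tolerance = 0.005)
})
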