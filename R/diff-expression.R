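## ------------------------------------------------------------------
## Differential circRNA expression: TMM-style between-sample
## normalisation and a per-feature negative-binomial quasi-likelihood
## F-test (Cox-Reid-adjusted profile dispersion, shrunk toward the
## mean-dispersion trend; deviance-based QL F statistic with an
## empirical-Bayes-squeezed denominator).
## ------------------------------------------------------------------

#' Benjamini-Hochberg adjustment with input validation
#'
#' Standard step-up BH with monotonicity enforcement (delegates to
#' [stats::p.adjust()]); errors on p-values outside `[0, 1]`. Invariant
#' to permutation of the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_config("p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' TMM-style normalisation factors and effective library sizes
#'
#' Trimmed-mean-of-M-values scaling: the reference is the column whose
#' log library size is closest to the mean log size; per column, log2
#' expression ratios against the reference are trimmed (30% each tail on
#' M, 5% each tail on abundance A) and averaged; factors are centred so
#' their geometric mean is 1. Effective library size = raw size x
#' factor.
#'
#' @param counts feature-by-sample count matrix (>= 2 samples).
#' @param lib_sizes optional library sizes (default column sums).
#' @return list with `factors`, `lib_sizes`, `effective` (named by
#'   sample) and `ref` (reference sample).
#' @export
normalize_tmm <- function(counts, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop_config("need at least 2 samples")
  lib_sizes <- lib_sizes %||% colSums(counts)
  zero <- lib_sizes == 0
  if (any(zero))
    stop_config("sample '%s' has an all-zero library",
                colnames(counts)[zero][1])
  ref <- which.min(abs(log(lib_sizes) - mean(log(lib_sizes))))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    keep <- counts[, j] > 0 & counts[, ref] > 0
    if (!any(keep)) return(1)
    pj <- counts[keep, j] / lib_sizes[j]
    pr <- counts[keep, ref] / lib_sizes[ref]
    M <- log2(pj / pr); A <- 0.5 * log2(pj * pr)
    qm <- stats::quantile(M, c(0.3, 0.7), names = FALSE, type = 7)
    qa <- stats::quantile(A, c(0.05, 0.95), names = FALSE, type = 7)
    k <- M >= qm[1] & M <= qm[2] & A >= qa[1] & A <= qa[2]
    if (!any(k)) k <- rep(TRUE, length(M))
    2^mean(M[k])
  }, numeric(1))
  f <- f / exp(mean(log(f)))               # geometric-mean centring
  eff <- lib_sizes * f
  names(f) <- names(eff) <- colnames(counts)
  list(factors = f, lib_sizes = lib_sizes, effective = eff,
       ref = colnames(counts)[ref])
}

## --- NB fitting machinery -----------------------------------------

## Fit one group mean on the count scale: solve sum (y - q*N)/(1+phi*q*N)=0
## for q by Newton on t = log q.
nb_fit_group <- function(y, N, phi) {
  if (sum(y) == 0) return(1e-10)
  t <- log(sum(y) / sum(N))
  for (it in 1:25) {
    mu <- exp(t) * N
    w <- 1 + phi * mu
    score <- sum((y - mu) / w)
    info <- sum(mu / w)
    step <- score / info
    step <- max(min(step, 2), -2)
    t <- t + step
    if (abs(step) < 1e-10) break
  }
  exp(t)
}

nb_deviance <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (phi <= 1e-12) {
    2 * sum(t1 - (y - mu))
  } else {
    2 * sum(t1 - (y + 1 / phi) * log((1 + phi * y) / (1 + phi * mu)))
  }
}

nb_loglik <- function(y, mu, phi) {
  phi <- max(phi, 1e-12)
  r <- 1 / phi
  sum(lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
        y * log(phi * mu / (1 + phi * mu)) - r * log(1 + phi * mu))
}

## Cox-Reid adjusted profile log-likelihood of phi for a one-factor
## design with offsets N (relative effective library sizes).
nb_profile_apl <- function(phi, y, N, grp) {
  ll <- 0; adj <- 0
  for (g in levels(grp)) {
    sel <- grp == g
    q <- nb_fit_group(y[sel], N[sel], phi)
    mu <- q * N[sel]
    ll <- ll + nb_loglik(y[sel], mu, phi)
    adj <- adj + 0.5 * log(sum(mu / (1 + phi * mu)))
  }
  ll - adj
}

#' Negative-binomial quasi-likelihood test for a two-group contrast
#'
#' Per feature, fits an intercept + genotype NB log-linear model with
#' effective-library-size offsets. Dispersion is estimated by Cox-Reid
#' adjusted profile likelihood, shrunk toward the mean-dispersion trend
#' with `prior_df` prior degrees of freedom; the genotype contrast is
#' tested with a quasi-likelihood F statistic whose denominator is the
#' empirical-Bayes-squeezed residual deviance scale
#' ([limma::squeezeVar]). log2 fold changes are mutant over reference
#' with a prior count of 0.125 added to each group mean (use
#' `paper_sign = TRUE` for the reference-over-mutant orientation).
#'
#' @param counts feature-by-sample integer count matrix.
#' @param genotype character/factor of length `ncol(counts)`; the
#'   reference (wild-type) level is `ref_level`.
#' @param ref_level reference genotype (default first level or `"WT"` if
#'   present).
#' @param effective_lib effective library sizes (default: TMM-normalised
#'   column sums via [normalize_tmm()]).
#' @param prior_df prior degrees of freedom for dispersion shrinkage
#'   (default 10).
#' @param prior_count prior count per group mean for finite log2FC
#'   (default 0.125).
#' @param paper_sign if `TRUE`, report log2FC as reference/mutant.
#' @return data.frame of class `"nova_de"`: `feature`, `log2FC`,
#'   `logCPM`-style mean abundance (`avg_norm`), `PValue`, `FDR`.
#'   Features with all-zero counts are excluded and listed in attribute
#'   `excluded`.
#' @export
fit_nb_test <- function(counts, genotype, ref_level = NULL,
                        effective_lib = NULL, prior_df = 10,
                        prior_count = 0.125, paper_sign = FALSE) {
  counts <- as.matrix(counts)
  genotype <- as.character(genotype)
  if (length(genotype) != ncol(counts))
    stop_config("genotype must have one entry per sample")
  lv <- unique(genotype)
  if (length(lv) != 2L) stop_config("exactly two genotypes required")
  ref_level <- ref_level %||% (if ("WT" %in% lv) "WT" else lv[1])
  grp <- factor(genotype, levels = c(ref_level, setdiff(lv, ref_level)))
  if (min(table(grp)) < 2L) stop_config("need >= 2 replicates per genotype")

  if (is.null(effective_lib))
    effective_lib <- normalize_tmm(counts)$effective
  N <- effective_lib / exp(mean(log(effective_lib)))   # relative offsets

  nonzero <- rowSums(counts) > 0
  excluded <- rownames(counts)[!nonzero]
  y_all <- counts[nonzero, , drop = FALSE]
  G <- nrow(y_all)
  if (G == 0L) stop_config("no non-zero features to test")

  df_res <- ncol(y_all) - 2L
  phi_hat <- numeric(G)
  for (g in seq_len(G)) {
    y <- y_all[g, ]
    op <- stats::optimize(function(lp) -nb_profile_apl(exp(lp), y, N, grp),
                          interval = c(log(1e-6), log(5)), tol = 1e-3)
    phi_hat[g] <- exp(op$minimum)
  }
  abund <- rowMeans(sweep(y_all, 2L, N, "/"))
  phi_trend <- if (G >= 50L) {
    lo <- stats::lowess(log(abund + 0.5), phi_hat, f = 0.5)
    pmax(stats::approx(lo$x, lo$y, xout = log(abund + 0.5), rule = 2,
                       ties = mean)$y, 1e-6)
  } else rep(max(mean(phi_hat), 1e-6), G)
  phi_sh <- (prior_df * phi_trend + df_res * phi_hat) / (prior_df + df_res)

  log2fc <- numeric(G); dev_drop <- numeric(G); s2 <- numeric(G)
  sel_ref <- grp == levels(grp)[1]
  for (g in seq_len(G)) {
    y <- y_all[g, ]; phi <- phi_sh[g]
    q1 <- nb_fit_group(y[sel_ref], N[sel_ref], phi)
    q2 <- nb_fit_group(y[!sel_ref], N[!sel_ref], phi)
    q0 <- nb_fit_group(y, N, phi)
    mu_full <- ifelse(sel_ref, q1, q2) * N
    d_full <- nb_deviance(y, mu_full, phi)
    d_null <- nb_deviance(y, q0 * N, phi)
    dev_drop[g] <- max(d_null - d_full, 0)
    s2[g] <- d_full / df_res
    log2fc[g] <- log2((q2 + prior_count) / (q1 + prior_count))
  }
  sq <- limma::squeezeVar(pmax(s2, 1e-10), df = df_res)
  df2 <- sq$df.prior + df_res
  Fstat <- dev_drop / pmax(sq$var.post, 1e-10)
  pval <- stats::pf(Fstat, 1, pmin(df2, 1e6), lower.tail = FALSE)
  pval[pval <= 0] <- .Machine$double.xmin

  if (paper_sign) log2fc <- -log2fc
  out <- data.frame(feature = rownames(y_all) %||% as.character(seq_len(G)),
                    log2FC = log2fc, avg_norm = abund,
                    dispersion = phi_sh, F = Fstat, PValue = pval,
                    FDR = bh_adjust(pval), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "df2") <- df2
  class(out) <- c("nova_de", "data.frame")
  out
}

#' Classify differential-expression results
#'
#' `up` means higher in the mutant: `log2FC > lfc_threshold` with the
#' gating p-value below `p_threshold`; `down` is the mirror image;
#' everything else is `ns`. The gate uses the raw p-value by default
#' (`use = "fdr"` gates on BH-adjusted values instead). The minimum
#' detectable fold change implied by the default threshold is
#' `2^0.5 ~ 1.41`.
#'
#' @param results a [fit_nb_test()] data.frame.
#' @param lfc_threshold absolute log2FC threshold (default 0.5).
#' @param p_threshold significance threshold (default 0.05).
#' @param use `"p"` (default) or `"fdr"`.
#' @return `results` with a `call` column (`up`/`down`/`ns`).
#' @export
classify_de <- function(results, lfc_threshold = 0.5, p_threshold = 0.05,
                        use = c("p", "fdr")) {
  use <- match.arg(use)
  if (lfc_threshold <= 0 || p_threshold <= 0)
    stop_config("thresholds must be positive")
  gate <- if (use == "p") results$PValue else results$FDR
  call <- rep("ns", nrow(results))
  call[results$log2FC > lfc_threshold & gate < p_threshold] <- "up"
  call[results$log2FC < -lfc_threshold & gate < p_threshold] <- "down"
  results$call <- call
  results
}

#' Minimum detectable fold change for a log2FC threshold
#'
#' @param lfc_threshold absolute log2 fold-change threshold.
#' @return `2^lfc_threshold` (e.g. ~1.41 for the default 0.5).
#' @export
min_fold_change <- function(lfc_threshold = 0.5) 2^lfc_threshold
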