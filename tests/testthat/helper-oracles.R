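## Independent brute-force oracles used across the suite.  These stay
## deliberately naive and separate from the package implementations.

## Exhaustive sliding 4-mer window count of YCAY occurrences.
oracle_ycay <- function(s) {
  n <- nchar(s)
  if (n < 4L) return(0L)
  hits <- 0L
  for (i in seq_len(n - 3L)) {
    w <- substr(s, i, i + 3L)
    if (substr(w, 1, 1) %in% c("C", "T") && substr(w, 2, 2) == "C" &&
        substr(w, 3, 3) == "A" && substr(w, 4, 4) %in% c("C", "T"))
      hits <- hits + 1L
  }
  hits
}

## Textbook Benjamini-Hochberg step-up (sort, multiply, cummin from the
## largest rank, restore order).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

## Mantel-Cox log-rank chi-squared by explicit risk-set tabulation.
oracle_logrank <- function(day, dead, group) {
  times <- sort(unique(day[dead == 1]))
  OmE <- 0; V <- 0
  for (t in times) {
    at_risk <- day >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == group[1])
    d <- sum(day == t & dead == 1)
    d1 <- sum(day == t & dead == 1 & group == group[1])
    e1 <- d * n1 / n
    OmE <- OmE + d1 - e1
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  OmE^2 / V
}

## Collapse a set of read-pair placement tuples to unique count.
oracle_collapse <- function(keys) length(unique(keys))

## Two-group binomial likelihood-ratio statistic on pooled counts.
oracle_binom_lrt <- function(I, n, grp) {
  ll <- function(I, n, p) sum(dbinom(I, n, p, log = TRUE))
  p0 <- sum(I) / sum(n)
  l0 <- ll(I, n, p0)
  l1 <- 0
  for (g in unique(grp)) {
    sel <- grp == g
    l1 <- l1 + ll(I[sel], n[sel], sum(I[sel]) / sum(n[sel]))
  }
  2 * (l1 - l0)
}

## Convenience: the default fixture/sim pair used by several files.
make_test_sim <- function(seed = 42, ...) {
  fx <- make_fixture(fixture_config(seed = seed))
  list(fx = fx, sim = simulate_reads(fx, ...))
}

## Deterministic sequence of given length with exactly k YCAY sites
## (all-G background, TCAC planted at spaced offsets).
plant_ycay_str <- function(len, k) {
  s <- strrep("G", len)
  if (k > 0) {
    pos <- floor(seq(5, len - 8, length.out = k))
    for (p in pos) substr(s, p, p + 3) <- "TCAC"
  }
  stopifnot(oracle_ycay(s) == k)
  s
}
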