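## ------------------------------------------------------------------
## Linear alternative splicing: junction scaffolds for the five event
## classes (SE, A3'SS, A5'SS, RI, MXE), inclusion/skipping read
## counting, length-normalised PSI, and a replicate-aware beta-binomial
## likelihood-ratio test with the WT-minus-mutant dPSI orientation.
## ------------------------------------------------------------------

#' Build linear junction scaffolds for one splicing event
#'
#' Each splice junction defining the event becomes a
#' `2 * flank`-nt scaffold (flank nt of spliced context on each side of
#' the seam); retained-intron boundary "junctions" (where
#' `left_end == right_start`) become contiguous genomic windows centred
#' on the boundary. Minus-strand events are reverse-complemented.
#'
#' @param event a `splice_event` (see [make_fixture()]).
#' @param genome a `toy_genome`.
#' @param flank context length per side in nt (default 150, one read
#'   length).
#' @return list with elements `inclusion` and `skipping`, each a list of
#'   scaffolds (`id`, `seq`, `seam`).
#' @export
event_scaffolds <- function(event, genome, flank = 150L) {
  cs <- genome[[event$contig]]
  mk <- function(jx, tag, i) {
    le <- jx[["left_end"]]; rs <- jx[["right_start"]]
    if (le - flank < 0 || rs + flank > nchar(cs))
      stop_config("event %s junction window outside contig", event$event_id)
    sq <- paste0(subseq0(cs, le - flank, le), subseq0(cs, rs, rs + flank))
    if (identical(event$strand, "-")) sq <- revcomp(sq)
    list(id = sprintf("%s_%s%d", event$event_id, tag, i), seq = sq,
         seam = flank)
  }
  list(inclusion = Map(mk, event$inclusion, "I",
                       seq_along(event$inclusion)),
       skipping = Map(mk, event$skipping, "S", seq_along(event$skipping)))
}

#' Effective form lengths (distinct supporting read positions)
#'
#' In `"jc"` (junction-count) mode the effective length of a form is the
#' number of distinct read start positions spanning its junctions with
#' the required overhang: `(read_len - 2 * overhang + 1)` per junction.
#' `"jcec"` additionally credits exon-body positions of the alternative
#' region (cassette exon, retained intron, or mutually exclusive exon)
#' to the corresponding form when the region is at least one read long.
#'
#' @param event a `splice_event`.
#' @param read_len read length (default 150).
#' @param overhang junction overhang (default 8).
#' @param mode `"jc"` (default) or `"jcec"`.
#' @return named numeric vector `c(l_I, l_S)`.
#' @export
effective_lengths <- function(event, read_len = 150L, overhang = 8L,
                              mode = c("jc", "jcec")) {
  mode <- match.arg(mode)
  per_j <- read_len - 2L * overhang + 1L
  if (per_j < 1L)
    stop_config("event junction shorter than the overhang window")
  l_I <- length(event$inclusion) * per_j
  l_S <- length(event$skipping) * per_j
  if (mode == "jcec") {
    body <- function(lo, hi) max(0L, (hi - lo) - read_len + 1L)
    if (event$type %in% c("SE", "RI")) {
      l_I <- l_I + body(event$inclusion[[1]][["right_start"]],
                        event$inclusion[[2]][["left_end"]])
    } else if (event$type == "MXE") {
      l_I <- l_I + body(event$inclusion[[1]][["right_start"]],
                        event$inclusion[[2]][["left_end"]])
      l_S <- l_S + body(event$skipping[[1]][["right_start"]],
                        event$skipping[[2]][["left_end"]])
    }
    ## A3SS/A5SS alternative regions are shorter than a read here: no body
  }
  c(l_I = l_I, l_S = l_S)
}

#' Count inclusion and skipping read pairs for one splicing event
#'
#' Pairs are assigned by exact matching of the seam-spanning mate
#' (either orientation) into the event's junction scaffolds with at
#' least `min_overhang` nt on each side of the seam. A pair whose
#' spanning matches touch both forms is ambiguous and dropped (tallied);
#' a pair with no spanning match is uninformative for the event.
#' Duplicate pairs (same scaffold, offset, mate-offset) are collapsed.
#'
#' @param event a `splice_event`.
#' @param reads named list of per-sample data.frames (`r1`, `r2`), or a
#'   single data.frame.
#' @param genome a `toy_genome`.
#' @param min_overhang minimum seam overhang (default 8).
#' @param flank scaffold context per side (default 150).
#' @return data.frame `event_id`, `sample`, `I`, `S` with attribute
#'   `tallies` (ambiguous pairs per sample).
#' @export
count_event_reads <- function(event, reads, genome, min_overhang = 8L,
                              flank = 150L) {
  if (is.data.frame(reads)) reads <- list(S1 = reads)
  es <- event_scaffolds(event, genome, flank = flank)
  scafs <- c(es$inclusion, es$skipping)
  form <- rep(c("I", "S"), c(length(es$inclusion), length(es$skipping)))
  sq <- vapply(scafs, `[[`, character(1), "seq")
  seam <- vapply(scafs, function(s) as.integer(s$seam), integer(1))

  rows <- list(); tallies <- stats::setNames(integer(length(reads)),
                                             names(reads))
  for (smp in names(reads)) {
    df <- reads[[smp]]
    keysI <- character(0); keysS <- character(0); ambiguous <- 0L
    if (nrow(df) > 0L) {
      rc1 <- revcomp(df$r1); rc2 <- revcomp(df$r2)
      for (i in seq_len(nrow(df))) {
        o1 <- vapply(sq, function(s) match_one(df$r1[i], rc1[i], s),
                     integer(1), USE.NAMES = FALSE)
        o2 <- vapply(sq, function(s) match_one(df$r2[i], rc2[i], s),
                     integer(1), USE.NAMES = FALSE)
        sp <- spans_seam(o1, nchar(df$r1[i]), seam, min_overhang) |
          spans_seam(o2, nchar(df$r2[i]), seam, min_overhang)
        hit <- which(sp)
        if (length(hit) == 0L) next
        forms <- unique(form[hit])
        if (length(forms) > 1L) { ambiguous <- ambiguous + 1L; next }
        j <- hit[1L]
        key <- paste(j, o1[j], o2[j])
        if (forms == "I") keysI <- c(keysI, key) else keysS <- c(keysS, key)
      }
    }
    rows[[smp]] <- data.frame(event_id = event$event_id, sample = smp,
                              I = length(unique(keysI)),
                              S = length(unique(keysS)),
                              stringsAsFactors = FALSE)
    tallies[smp] <- ambiguous
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tallies") <- tallies
  out
}

#' Length-normalised percent spliced in
#'
#' `PSI = (I / l_I) / (I / l_I + S / l_S)`; `NA` when `I + S == 0`
#' (sample dropped for the event, to be tallied by the caller).
#' Scale-invariant in `(I, S)` and equal to `I / (I + S)` when
#' `l_I == l_S`.
#'
#' @param I,S inclusion and skipping read counts (vectors).
#' @param l_I,l_S effective form lengths (defaults 1).
#' @return PSI values in `[0, 1]`, `NA` where undefined.
#' @export
compute_psi <- function(I, S, l_I = 1, l_S = 1) {
  if (any(l_I < 1) || any(l_S < 1)) stop_config("effective lengths must be >= 1")
  num <- I / l_I; den <- num + S / l_S
  ifelse(den > 0, num / den, NA_real_)
}

## --- beta-binomial likelihood machinery ---------------------------

bb_negll <- function(I, n, p, rho) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  if (rho < 1e-9) {
    -sum(stats::dbinom(I, n, p, log = TRUE))
  } else {
    a <- p * (1 - rho) / rho; b <- (1 - p) * (1 - rho) / rho
    -sum(lchoose(n, I) + lbeta(I + a, n - I + b) - lbeta(a, b))
  }
}

## maximise BB likelihood; grp_idx NULL => common p, else p per group
bb_fit <- function(I, n, grp_idx = NULL, rho = NULL) {
  pool_p <- function(sel) {
    p <- sum(I[sel]) / max(sum(n[sel]), 1)
    pmin(pmax(p, 1e-6), 1 - 1e-6)
  }
  logit <- function(x) log(x / (1 - x))
  if (is.null(grp_idx)) {
    p0 <- pool_p(rep(TRUE, length(I)))
    nll_fixed_rho <- function(r) bb_negll(I, n, p0, r)
    if (!is.null(rho)) {
      ## still profile p for the fixed rho
      op <- stats::optimize(function(lp) bb_negll(I, n, stats::plogis(lp), rho),
                            interval = c(-15, 15), tol = 1e-8)
      return(list(ll = -op$objective, p = stats::plogis(op$minimum),
                  rho = rho))
    }
    op <- stats::optim(c(logit(p0), logit(0.05)), function(par)
      bb_negll(I, n, stats::plogis(par[1]), stats::plogis(par[2]) * 0.99),
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 2000))
    bin <- stats::optimize(function(lp)
      bb_negll(I, n, stats::plogis(lp), 0), interval = c(-15, 15),
      tol = 1e-8)
    if (bin$objective < op$value)
      list(ll = -bin$objective, p = stats::plogis(bin$minimum), rho = 0)
    else
      list(ll = -op$value, p = stats::plogis(op$par[1]),
           rho = stats::plogis(op$par[2]) * 0.99)
  } else {
    gl <- sort(unique(grp_idx))
    p_init <- vapply(gl, function(g) pool_p(grp_idx == g), numeric(1))
    nll2 <- function(par, rho_val) {
      nll <- 0
      for (k in seq_along(gl)) {
        sel <- grp_idx == gl[k]
        nll <- nll + bb_negll(I[sel], n[sel], stats::plogis(par[k]), rho_val)
      }
      nll
    }
    if (!is.null(rho)) {
      op <- stats::optim(logit(p_init), nll2, rho_val = rho,
                         method = if (length(gl) > 1) "Nelder-Mead" else "BFGS",
                         control = list(reltol = 1e-12, maxit = 2000))
      return(list(ll = -op$value, p = stats::plogis(op$par), rho = rho))
    }
    op <- stats::optim(c(logit(p_init), logit(0.05)), function(par)
      nll2(par[seq_along(gl)], stats::plogis(par[length(par)]) * 0.99),
      method = "Nelder-Mead",
      control = list(reltol = 1e-12, maxit = 3000))
    bin <- stats::optim(logit(p_init), nll2, rho_val = 0,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    if (bin$value < op$value)
      list(ll = -bin$value, p = stats::plogis(bin$par), rho = 0)
    else
      list(ll = -op$value, p = stats::plogis(op$par[seq_along(gl)]),
           rho = stats::plogis(op$par[length(op$par)]) * 0.99)
  }
}

#' Beta-binomial likelihood-ratio test for a two-group PSI difference
#'
#' Inclusion counts are modelled as beta-binomial draws from the total
#' event reads with a common overdispersion; the null holds one
#' inclusion proportion across groups, the alternative one per group.
#' By default the likelihood ratio is referred to F(1, n - 2) (n =
#' samples with defined PSI), a small-sample correction that keeps the
#' test calibrated at replicate numbers typical of these designs;
#' `null_dist = "chisq"` uses the asymptotic chi-squared(1) reference.
#' dPSI is reported as mean reference-group (wild-type) PSI minus mean
#' other-group PSI.
#'
#' @param I,S per-sample inclusion and skipping counts.
#' @param groups group labels, one per sample (2 groups).
#' @param ref_group reference (wild-type) group for the dPSI
#'   orientation; default `"WT"` if present, else the first label.
#' @param l_I,l_S effective form lengths for PSI reporting (default 1).
#' @param rho fix the overdispersion (e.g. `0` for a pure binomial LRT);
#'   `NULL` (default) profiles it.
#' @param null_dist `"f"` (default) or `"chisq"`.
#' @return list with `delta_psi`, `p_value`, `psi` (per sample),
#'   `group_means`, `lrt`, `rho`.
#' @export
test_event <- function(I, S, groups, ref_group = NULL, l_I = 1, l_S = 1,
                       rho = NULL, null_dist = c("f", "chisq")) {
  null_dist <- match.arg(null_dist)
  groups <- as.character(groups)
  stopifnot(length(I) == length(S), length(groups) == length(I))
  lv <- unique(groups)
  if (length(lv) != 2L) stop_config("exactly two groups required")
  ref_group <- ref_group %||% (if ("WT" %in% lv) "WT" else lv[1])
  other <- setdiff(lv, ref_group)
  n <- I + S
  ok <- n > 0
  if (sum(ok & groups == ref_group) < 2L || sum(ok & groups == other) < 2L)
    stop_config("need >= 2 replicates with defined PSI per group")
  psi <- compute_psi(I, S, l_I, l_S)
  gm <- c(mean(psi[ok & groups == ref_group]),
          mean(psi[ok & groups == other]))
  names(gm) <- c(ref_group, other)
  delta <- unname(gm[1] - gm[2])

  Iu <- I[ok]; nu <- n[ok]; gu <- groups[ok]
  if (all(Iu == 0) || all(Iu == nu)) {
    return(list(delta_psi = delta, p_value = 1, psi = psi, group_means = gm,
                lrt = 0, rho = 0))
  }
  grp_idx <- as.integer(gu == other) + 1L
  f0 <- bb_fit(Iu, nu, grp_idx = NULL, rho = rho)
  f1 <- bb_fit(Iu, nu, grp_idx = grp_idx, rho = rho)
  lrt <- max(2 * (f1$ll - f0$ll), 0)
  pv <- if (null_dist == "f")
    stats::pf(lrt, 1, max(sum(ok) - 2L, 1L), lower.tail = FALSE)
  else stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  list(delta_psi = delta, p_value = pv,
       psi = psi, group_means = gm, lrt = lrt, rho = f1$rho)
}

#' Test a table of splicing events and assemble rMATS-style results
#'
#' @param event_counts long data.frame with columns `event_id`,
#'   `sample`, `I`, `S` (e.g. rbind of [count_event_reads()] results).
#' @param groups named group vector (names = samples) or a vector
#'   aligned with the samples of each event.
#' @param events optional named list of `splice_event`s, used to attach
#'   `type`/`gene_id` and compute effective lengths.
#' @param read_len,overhang,mode passed to [effective_lengths()] when
#'   `events` is given; otherwise lengths default to 1.
#' @param ref_group reference group for the dPSI orientation.
#' @return data.frame of class `"nova_psi"` with rMATS-flavoured
#'   columns: `event_id`, `type`, `gene_id`, `IJC1`, `SJC1`, `IJC2`,
#'   `SJC2` (comma-separated per-replicate counts), `IncFormLen`,
#'   `SkipFormLen`, `IncLevel1`, `IncLevel2`, `IncLevelDifference`
#'   (reference minus other), `PValue`, `FDR`.
#' @export
psi_test_table <- function(event_counts, groups, events = NULL,
                           read_len = 150L, overhang = 8L,
                           mode = c("jc", "jcec"), ref_group = NULL) {
  mode <- match.arg(mode)
  rows <- list()
  for (eid in unique(event_counts$event_id)) {
    d <- event_counts[event_counts$event_id == eid, , drop = FALSE]
    g <- if (!is.null(names(groups))) unname(groups[d$sample])
         else as.character(groups)
    rg <- ref_group %||% (if ("WT" %in% g) "WT" else g[1])
    og <- setdiff(unique(g), rg)
    ev <- events[[eid]]
    ll <- if (!is.null(ev))
      effective_lengths(ev, read_len, overhang, mode) else c(l_I = 1, l_S = 1)
    tt <- test_event(d$I, d$S, g, ref_group = rg,
                     l_I = ll[["l_I"]], l_S = ll[["l_S"]])
    sel1 <- g == rg
    rows[[eid]] <- data.frame(
      event_id = eid,
      type = if (!is.null(ev)) ev$type else NA_character_,
      gene_id = if (!is.null(ev)) ev$gene_id else NA_character_,
      IJC1 = paste(d$I[sel1], collapse = ","),
      SJC1 = paste(d$S[sel1], collapse = ","),
      IJC2 = paste(d$I[!sel1], collapse = ","),
      SJC2 = paste(d$S[!sel1], collapse = ","),
      IncFormLen = unname(ll[["l_I"]]), SkipFormLen = unname(ll[["l_S"]]),
      IncLevel1 = unname(tt$group_means[rg]),
      IncLevel2 = unname(tt$group_means[og]),
      IncLevelDifference = tt$delta_psi,
      PValue = tt$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$FDR <- bh_adjust(out$PValue)
  class(out) <- c("nova_psi", "data.frame")
  out
}

#' Select significant splicing events and summarise by type
#'
#' Keeps events with `FDR <= fdr` and `|dPSI| >= dpsi` (defaults 0.05
#' and 0.2: splicing changes of at least 20%).
#'
#' @param results a [psi_test_table()] data.frame (an `FDR` column is
#'   added via [bh_adjust()] if absent).
#' @param fdr FDR threshold (default 0.05).
#' @param dpsi absolute dPSI threshold (default 0.2).
#' @return list with `significant` (filtered data.frame) and `summary`
#'   (data.frame of counts per event type, the pie-chart input).
#' @export
filter_events <- function(results, fdr = 0.05, dpsi = 0.2) {
  if (nrow(results) == 0L)
    return(list(significant = results,
                summary = data.frame(type = character(0), n = integer(0))))
  if (is.null(results$FDR)) results$FDR <- bh_adjust(results$PValue)
  keep <- results$FDR <= fdr & abs(results$IncLevelDifference) >= dpsi
  sig <- results[keep, , drop = FALSE]
  rownames(sig) <- NULL
  tab <- if (nrow(sig) > 0L) as.data.frame(table(type = sig$type),
                                           stringsAsFactors = FALSE)
         else data.frame(type = character(0), Freq = integer(0))
  names(tab) <- c("type", "n")
  list(significant = sig, summary = tab)
}
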