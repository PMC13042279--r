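## ------------------------------------------------------------------
## Read-level simulator: junction-informative paired-end reads with
## ground truth.  Reads are emitted only over junction windows (BSJ
## scaffolds for circRNAs, splice-junction scaffolds for linear events),
## so exact substring matching downstream is a complete observation
## model.  PCR duplicates are byte-identical re-emissions of an existing
## pair; biological pairs are drawn without replacement over the
## (start, mate-start) grid so that the unique (deduplicated) count per
## feature equals the drawn negative-binomial count exactly.
## ------------------------------------------------------------------

#' Simulate paired-end junction reads with ground truth
#'
#' For each sample (2 genotypes x `n_reps` replicates) draws a
#' negative-binomial number of back-splice-junction read pairs per
#' circRNA (genotype effects applied as log2 fold changes on the mean)
#' and, per linear splicing event, a negative-binomial total depth split
#' binomially between inclusion and skipping junctions according to the
#' true PSI weighted by the number of distinct junction read positions.
#' Read 1 always spans a junction seam with at least `overhang` nt on
#' each side; read 2 is the reverse-complemented mate window.
#'
#' @param fixture a [make_fixture()] result.
#' @param n_reps,read_len,overhang,dup_fraction,phi,event_depth override
#'   the corresponding [fixture_config()] values if non-`NULL`.
#' @param seed seed for the read-level randomness (defaults to the
#'   fixture seed + 1).
#' @return an object of class `"sim_reads"`: list with `samples` (named
#'   list of data.frames with columns `id`, `r1`, `r2`, `origin`),
#'   `truth` (list: `circ_unique` and `circ_raw` feature-by-sample
#'   matrices, `events` long data.frame with per-sample `I`, `S` and
#'   `psi_true`, `genotype` named vector), and `config`.
#' @export
simulate_reads <- function(fixture, n_reps = NULL, read_len = NULL,
                           overhang = NULL, dup_fraction = NULL, phi = NULL,
                           event_depth = NULL, seed = NULL) {
  stopifnot(inherits(fixture, "nova_fixture"))
  cfg <- fixture$config
  cfg$n_reps <- as.integer(n_reps %||% cfg$n_reps)
  cfg$read_len <- as.integer(read_len %||% cfg$read_len)
  cfg$overhang <- as.integer(overhang %||% cfg$overhang)
  cfg$dup_fraction <- dup_fraction %||% cfg$dup_fraction
  cfg$phi <- phi %||% cfg$phi
  cfg$event_depth <- event_depth %||% cfg$event_depth
  seed <- as.integer(seed %||% (cfg$seed + 1L))
  if (cfg$overhang > cfg$read_len / 2)
    stop_config("overhang (%d) may not exceed half the read length (%d)",
                cfg$overhang, cfg$read_len)
  if (cfg$dup_fraction < 0 || cfg$dup_fraction >= 1)
    stop_config("dup_fraction must lie in [0, 1)")
  withr::with_seed(seed, simulate_reads_impl(fixture, cfg, seed))
}

simulate_reads_impl <- function(fixture, cfg, seed) {
  L <- cfg$read_len; oh <- cfg$overhang
  samples <- paste0(rep(cfg$genotypes, each = cfg$n_reps), "_",
                    rep(seq_len(cfg$n_reps), times = 2L))
  genotype <- stats::setNames(rep(cfg$genotypes, each = cfg$n_reps), samples)

  circ_scafs <- lapply(seq_len(nrow(fixture$circs)), function(i)
    build_scaffold(fixture$circs[i, ], fixture$genome))
  names(circ_scafs) <- fixture$circs$circ_id
  ev_scafs <- lapply(fixture$events, event_scaffolds, genome = fixture$genome,
                     flank = L)

  nC <- nrow(fixture$circs)
  circ_unique <- matrix(0L, nC, length(samples),
                        dimnames = list(fixture$circs$circ_id, samples))
  circ_raw <- circ_unique
  ev_rows <- list()
  out_samples <- stats::setNames(vector("list", length(samples)), samples)

  for (s in samples) {
    is_mut <- genotype[[s]] != cfg$genotypes[1]
    r1 <- character(0); r2 <- character(0); origin <- character(0)

    ## --- circRNA BSJ read pairs -----------------------------------
    for (i in seq_len(nC)) {
      sc <- circ_scafs[[i]]
      mu <- fixture$circs$mean_wt[i] *
        if (is_mut) 2^fixture$circs$log2fc[i] else 1
      max_start <- nchar(sc$seq) - L            # 0-based start range 0..max
      ## seam-crossing starts for read 1
      s1_ok <- 0:max_start
      s1_ok <- s1_ok[s1_ok <= sc$seam - oh & s1_ok + L >= sc$seam + oh]
      grid <- length(s1_ok) * (max_start + 1L)
      n <- min(stats::rnbinom(1L, mu = mu, size = 1 / cfg$phi), grid)
      if (n > 0) {
        idx <- sample.int(grid, n) - 1L
        p1 <- s1_ok[idx %/% (max_start + 1L) + 1L]
        p2 <- idx %% (max_start + 1L)
        a <- substr(rep(sc$seq, n), p1 + 1L, p1 + L)
        b <- revcomp(substr(rep(sc$seq, n), p2 + 1L, p2 + L))
        ndup <- stats::rbinom(1L, n, cfg$dup_fraction)
        if (ndup > 0) {
          di <- sample.int(n, ndup, replace = TRUE)
          a <- c(a, a[di]); b <- c(b, b[di])
        }
        r1 <- c(r1, a); r2 <- c(r2, b)
        origin <- c(origin, rep(sc$circ_id, n + ndup))
        circ_unique[i, s] <- n
        circ_raw[i, s] <- n + ndup
      }
    }

    ## --- linear splicing event read pairs -------------------------
    for (ev in fixture$events) {
      es <- ev_scafs[[ev$event_id]]
      psi <- if (is_mut) ev$psi_mut else ev$psi_wt
      kI <- length(es$inclusion); kS <- length(es$skipping)
      p_read <- psi * kI / (psi * kI + (1 - psi) * kS)
      n <- stats::rnbinom(1L, mu = cfg$event_depth, size = 1 / cfg$phi)
      nI <- stats::rbinom(1L, n, p_read); nS <- n - nI
      emit <- function(scafs, m, tag) {
        if (m == 0) return(NULL)
        per_j <- nchar(scafs[[1]]$seq)      # all event scaffolds same size
        s1_ok <- oh:(per_j - L - oh)
        grid <- length(scafs) * length(s1_ok) * (per_j - L + 1L)
        m <- min(m, grid)
        idx <- sample.int(grid, m) - 1L
        j <- idx %/% (length(s1_ok) * (per_j - L + 1L)) + 1L
        rest <- idx %% (length(s1_ok) * (per_j - L + 1L))
        p1 <- s1_ok[rest %/% (per_j - L + 1L) + 1L]
        p2 <- rest %% (per_j - L + 1L)
        sq <- vapply(scafs, function(x) x$seq, character(1))[j]
        list(r1 = substr(sq, p1 + 1L, p1 + L),
             r2 = revcomp(substr(sq, p2 + 1L, p2 + L)),
             origin = rep(tag, m), m = m)
      }
      ei <- emit(es$inclusion, nI, paste0(ev$event_id, ":I"))
      esk <- emit(es$skipping, nS, paste0(ev$event_id, ":S"))
      for (e in list(ei, esk)) {
        if (!is.null(e)) {
          r1 <- c(r1, e$r1); r2 <- c(r2, e$r2); origin <- c(origin, e$origin)
        }
      }
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        event_id = ev$event_id, sample = s, genotype = unname(genotype[s]),
        I = if (is.null(ei)) 0L else ei$m,
        S = if (is.null(esk)) 0L else esk$m,
        psi_true = psi, stringsAsFactors = FALSE)
    }

    out_samples[[s]] <- data.frame(
      id = sprintf("%s_r%06d", s, seq_along(r1)),
      r1 = r1, r2 = r2, origin = origin, stringsAsFactors = FALSE)
  }

  structure(list(
    samples = out_samples,
    truth = list(circ_unique = circ_unique, circ_raw = circ_raw,
                 events = do.call(rbind, ev_rows), genotype = genotype,
                 phi = cfg$phi, dup_fraction = cfg$dup_fraction, seed = seed),
    config = cfg), class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads: ", length(x$samples), " samples, ",
      sum(vapply(x$samples, nrow, integer(1))), " read pairs (seed ",
      x$truth$seed, ")\n", sep = "")
  invisible(x)
}

#' Write simulated reads as paired FASTQ files
#'
#' One `<sample>_R1.fastq[.gz]` / `<sample>_R2.fastq[.gz]` pair per
#' sample, Phred+33 with uniform quality.
#'
#' @param sim a [simulate_reads()] result.
#' @param dir output directory.
#' @param gzip compress output (default `TRUE`).
#' @return invisibly, the paths written.
#' @export
write_fastq <- function(sim, dir, gzip = TRUE) {
  stopifnot(inherits(sim, "sim_reads"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- character(0)
  for (s in names(sim$samples)) {
    df <- sim$samples[[s]]
    for (mate in c("r1", "r2")) {
      p <- file.path(dir, paste0(s, "_", toupper(sub("r", "R", mate)), ext))
      sq <- Biostrings::DNAStringSet(df[[mate]])
      names(sq) <- paste0(df$id, "/", sub("r", "", mate))
      qual <- Biostrings::BStringSet(strrep("I", nchar(df[[mate]])))
      Biostrings::writeXStringSet(sq, p, format = "fastq", qualities = qual,
                                  compress = gzip)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read paired FASTQ files back into the in-memory pair format
#'
#' @param r1_path,r2_path FASTQ paths (may be gzipped).
#' @return data.frame with columns `id`, `r1`, `r2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  a <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  b <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  stopifnot(length(a) == length(b))
  data.frame(id = sub("/1$", "", names(a)), r1 = as.character(a),
             r2 = as.character(b), stringsAsFactors = FALSE)
}
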