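## ------------------------------------------------------------------
## Back-splice junction quantification: 200-nt junction scaffolds,
## exact split-read BSJ calling, duplicate-aware junction-read counting
## and the junction-read abundance filter.
## ------------------------------------------------------------------

#' Build a 200-nt back-splice junction scaffold
#'
#' The scaffold is a linear pseudo-reference across the back-splice
#' seam: the terminal 100 nt of the circle followed by its initial
#' 100 nt (transcript orientation; minus-strand circles are
#' reverse-complemented). Circles shorter than 100 nt per side are tiled
#' circularly.
#'
#' @param locus one circRNA locus: a list/data.frame row with `circ_id`,
#'   `contig`, `start`, `end` (0-based half-open) and `strand`.
#' @param genome a `toy_genome` (named character vector of contigs).
#' @param scaffold_len total scaffold length (default 200 nt).
#' @return list with `circ_id`, `seq` (length `scaffold_len`) and `seam`
#'   (0-based index of the back-splice seam, `scaffold_len / 2`).
#' @export
build_scaffold <- function(locus, genome, scaffold_len = 200L) {
  cs <- genome[[locus$contig]]
  if (is.null(cs) || locus$start < 0 || locus$end > nchar(cs) ||
      locus$start >= locus$end)
    stop_config("circ locus %s does not fit contig '%s'",
                locus$circ_id %||% "?", locus$contig)
  circ <- subseq0(cs, locus$start, locus$end)
  if (identical(locus$strand, "-")) circ <- revcomp(circ)
  half <- scaffold_len %/% 2L
  tiled <- strrep(circ, ceiling(half / nchar(circ)) + 1L)
  left <- substr(tiled, nchar(tiled) - half + 1L, nchar(tiled))
  right <- substr(tiled, 1L, half)
  list(circ_id = locus$circ_id, seq = paste0(left, right), seam = half)
}

#' Write junction scaffolds as FASTA
#'
#' Record ids are circ ids; the seam offset is carried in the
#' description line.
#'
#' @param scaffolds list of [build_scaffold()] results.
#' @param path output FASTA path.
#' @export
write_scaffolds <- function(scaffolds, path) {
  sq <- Biostrings::DNAStringSet(vapply(scaffolds, `[[`, character(1), "seq"))
  names(sq) <- vapply(scaffolds, function(s)
    sprintf("%s seam=%d", s$circ_id, s$seam), character(1))
  Biostrings::writeXStringSet(sq, path)
  invisible(path)
}

## length of common prefix / suffix of two strings
common_prefix_len <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  a <- charToRaw(substr(x, 1L, n)); b <- charToRaw(substr(y, 1L, n))
  d <- which(a != b)
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix_len <- function(x, y) {
  n <- min(nchar(x), nchar(y))
  if (n == 0L) return(0L)
  a <- charToRaw(substr(x, nchar(x) - n + 1L, nchar(x)))
  b <- charToRaw(substr(y, nchar(y) - n + 1L, nchar(y)))
  d <- which(rev(a != b))
  if (length(d) == 0L) n else d[1L] - 1L
}

kmer_index <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  km <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  pos <- split(seq_len(n) - 1L, km)       # 0-based positions
  list2env(pos, hash = TRUE, size = length(pos))
}

#' Call back-splice junctions from reads by exact split-read anchoring
#'
#' Simplified split-read BSJ caller: the first and last k-mers of a read
#' (or its reverse complement) are anchored exactly in the genome; a
#' pair of anchors in inverted genomic order on one contig defines a
#' candidate back-splice. The exact seam is found by maximal exact
#' extension of both anchors; when micro-homology makes several seams
#' consistent, the maximal prefix (donor-side) split is taken
#' (deterministic).
#'
#' @param reads character vector of read sequences, a data.frame with an
#'   `r1` column, or a named list of such data.frames (samples pooled).
#' @param genome a `toy_genome`.
#' @param k anchor k-mer length (default 20).
#' @param max_hits anchors occurring at more than this many genomic
#'   positions make a read ambiguous; it is skipped and tallied
#'   (default 4).
#' @param min_support minimum supporting split reads for a reported
#'   locus (default 2).
#' @param max_circ_len sanity cap on circle length (default 10000 nt).
#' @return data.frame of candidate loci (`contig`, `start`, `end`
#'   0-based half-open, `strand`, `support`), ordered by position, with
#'   attribute `tallies` recording skipped-read counts.
#' @export
call_bsj <- function(reads, genome, k = 20L, max_hits = 4L,
                     min_support = 2L, max_circ_len = 10000L) {
  if (is.list(reads) && !is.data.frame(reads))
    reads <- unlist(lapply(reads, function(d) d$r1), use.names = FALSE)
  if (is.data.frame(reads)) reads <- reads$r1
  contigs <- names(genome)
  idx <- lapply(contigs, function(cn) kmer_index(genome[[cn]], k))
  names(idx) <- contigs

  support <- new.env(hash = TRUE)
  ambiguous <- 0L; unanchored <- 0L
  rc <- revcomp(reads)

  for (ri in seq_along(reads)) {
    found <- FALSE
    for (orient in 1:2) {
      r <- if (orient == 1L) reads[[ri]] else rc[[ri]]
      L <- nchar(r)
      if (L < 2L * k) break
      ka <- substr(r, 1L, k); kb <- substr(r, L - k + 1L, L)
      for (cn in contigs) {
        g <- genome[[cn]]
        a_hits <- idx[[cn]][[ka]]; b_hits <- idx[[cn]][[kb]]
        if (is.null(a_hits) || is.null(b_hits)) next
        if (length(a_hits) > max_hits || length(b_hits) > max_hits) {
          ambiguous <- ambiguous + 1L
          next
        }
        for (a in a_hits) {
          for (b in b_hits) {
            if (b >= a) next                      # colinear or gapped: linear
            P <- common_prefix_len(r, subseq0(g, a, min(a + L, nchar(g))))
            M <- common_suffix_len(r, subseq0(g, max(0L, b + k - L), b + k))
            i_lo <- max(k, L - M); i_hi <- min(P, L - k)
            if (i_lo > i_hi) next
            i <- i_hi                 # maximal donor-side extension
            s0 <- b + k - L + i; e0 <- a + i
            if (s0 < 0L || s0 >= e0 || e0 - s0 > max_circ_len) next
            strand <- if (orient == 1L) "+" else "-"
            key <- paste(cn, s0, e0, strand, sep = "\r")
            support[[key]] <- (support[[key]] %||% 0L) + 1L
            found <- TRUE
            break
          }
          if (found) break
        }
        if (found) break
      }
      if (found) break
    }
  }

  keys <- ls(support)
  if (length(keys) == 0L) {
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      support = integer(0), stringsAsFactors = FALSE)
  } else {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    out <- data.frame(contig = parts[, 1L],
                      start = as.integer(parts[, 2L]),
                      end = as.integer(parts[, 3L]),
                      strand = parts[, 4L],
                      support = vapply(keys, function(k2) support[[k2]],
                                       integer(1)),
                      stringsAsFactors = FALSE)
    out <- out[out$support >= min_support, , drop = FALSE]
    out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "tallies") <- c(ambiguous = ambiguous, unanchored = unanchored)
  out
}

## does a 0-based match offset place the read across the seam with the
## required overhang on both sides?
spans_seam <- function(offset, read_len, seam, overhang) {
  !is.na(offset) & offset <= seam - overhang &
    offset + read_len >= seam + overhang
}

match_one <- function(seq, rc_seq, scaf_seq) {
  p <- regexpr(seq, scaf_seq, fixed = TRUE)[1L]
  if (p > 0L) return(p - 1L)
  p <- regexpr(rc_seq, scaf_seq, fixed = TRUE)[1L]
  if (p > 0L) p - 1L else NA_integer_
}

#' Count junction-spanning read pairs per scaffold, with deduplication
#'
#' Read pairs are placed into junction scaffolds by exact substring
#' matching (both orientations of both mates). A pair supports a
#' junction when either mate crosses the seam with at least
#' `min_overhang` nt on each side. Duplicates are pairs with identical
#' (scaffold, offset, mate-offset) and are collapsed into the unique
#' count. Pairs matching more than one scaffold are dropped and tallied.
#'
#' @param scaffolds list of [build_scaffold()] results.
#' @param reads a named list of per-sample data.frames with columns `r1`
#'   and `r2` (as from [simulate_reads()]`$samples`), or a single such
#'   data.frame (treated as one sample `"S1"`).
#' @param min_overhang minimum seam overhang in nt (default 8).
#' @return data.frame with columns `circ_id`, `sample`, `raw`, `unique`,
#'   one row per scaffold per sample, with attribute `tallies` (per
#'   sample: ambiguous pair count).
#' @export
count_junction_reads <- function(scaffolds, reads, min_overhang = 8L) {
  if (is.data.frame(reads)) reads <- list(S1 = reads)
  sc_ids <- vapply(scaffolds, `[[`, character(1), "circ_id")
  sc_seq <- vapply(scaffolds, `[[`, character(1), "seq")
  sc_seam <- vapply(scaffolds, function(s) as.integer(s$seam), integer(1))
  out <- list(); tallies <- stats::setNames(integer(length(reads)), names(reads))

  for (smp in names(reads)) {
    df <- reads[[smp]]
    raw <- stats::setNames(integer(length(scaffolds)), sc_ids)
    keys <- stats::setNames(vector("list", length(scaffolds)), sc_ids)
    ambiguous <- 0L
    if (nrow(df) > 0L) {
      rc1 <- revcomp(df$r1); rc2 <- revcomp(df$r2)
      for (i in seq_len(nrow(df))) {
        o1 <- rep(NA_integer_, length(scaffolds))
        o2 <- o1
        for (j in seq_along(scaffolds)) {
          o1[j] <- match_one(df$r1[i], rc1[i], sc_seq[j])
          o2[j] <- match_one(df$r2[i], rc2[i], sc_seq[j])
        }
        hit <- which(!is.na(o1) | !is.na(o2))
        if (length(hit) == 0L) next
        if (length(hit) > 1L) { ambiguous <- ambiguous + 1L; next }
        j <- hit
        supports <- spans_seam(o1[j], nchar(df$r1[i]), sc_seam[j], min_overhang) ||
          spans_seam(o2[j], nchar(df$r2[i]), sc_seam[j], min_overhang)
        if (!supports) next
        raw[j] <- raw[j] + 1L
        keys[[j]] <- c(keys[[j]], paste(o1[j], o2[j]))
      }
    }
    uniq <- vapply(keys, function(k) length(unique(k)), integer(1))
    out[[smp]] <- data.frame(circ_id = sc_ids, sample = smp,
                             raw = unname(raw), unique = unname(uniq),
                             stringsAsFactors = FALSE)
    tallies[smp] <- ambiguous
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "tallies") <- tallies
  res
}

#' Reshape long junction counts into a feature-by-sample matrix
#'
#' @param counts data.frame from [count_junction_reads()].
#' @param value `"unique"` (default) or `"raw"`.
#' @return integer matrix, circ ids by samples.
#' @export
junction_count_matrix <- function(counts, value = c("unique", "raw")) {
  value <- match.arg(value)
  ids <- unique(counts$circ_id); smp <- unique(counts$sample)
  m <- matrix(0L, length(ids), length(smp), dimnames = list(ids, smp))
  m[cbind(match(counts$circ_id, ids), match(counts$sample, smp))] <-
    counts[[value]]
  m
}

#' Filter circRNAs on pooled unique junction reads
#'
#' Removes features whose unique junction reads, pooled across samples,
#' fall below `min_junction_reads` (default 12, i.e. "junction reads
#' < 12" are filtered out). `scope = "per_sample"` instead requires
#' every sample to reach the threshold individually.
#'
#' @param counts feature-by-sample count matrix.
#' @param min_junction_reads minimum junction reads (default 12).
#' @param scope `"pooled"` (default) or `"per_sample"`.
#' @return the filtered matrix, row order preserved, with attribute
#'   `removed` naming the dropped features.
#' @export
filter_circ <- function(counts, min_junction_reads = 12L,
                        scope = c("pooled", "per_sample")) {
  scope <- match.arg(scope)
  if (min_junction_reads < 0) stop_config("min_junction_reads must be >= 0")
  if (nrow(counts) == 0L) return(counts)
  keep <- if (scope == "pooled") rowSums(counts) >= min_junction_reads
          else apply(counts, 1L, min) >= min_junction_reads
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(counts)[!keep]
  out
}
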