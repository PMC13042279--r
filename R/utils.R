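#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet
#' @importFrom withr with_seed
NULL

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over plain character vectors (ACGT
#' alphabet), delegating to Biostrings.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## 0-based half-open substring: returns sequence of [start, end)
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Remove every YCAY occurrence (incl. overlapping) by mutating the A -> G.
strip_ycay <- function(seq) {
  repeat {
    m <- gregexpr("(?=[CT]CA[CT])", seq, perl = TRUE)[[1]]
    if (m[1] == -1L) break
    for (p in m) substr(seq, p + 2L, p + 2L) <- "G"
  }
  seq
}

## Plant exactly k YCAY motifs as guarded GTCACG blocks into a YCAY-free
## sequence; guards prevent accidental windows at block edges.
plant_ycay <- function(seq, k, lo = 10L, hi = nchar(seq) - 12L) {
  if (k == 0L) return(seq)
  stopifnot(hi - lo >= 8L * k)
  pos <- floor(seq(lo, hi, length.out = k))
  for (p in pos) substr(seq, p + 1L, p + 6L) <- "GTCACG"
  out <- count_ycay(seq)
  stopifnot(out == k)
  seq
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
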