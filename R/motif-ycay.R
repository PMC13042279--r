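## ------------------------------------------------------------------
## NOVA YCAY ([CT]CA[CT]) motif scanning: sliding-window counts with
## overlaps, per-transcript exon/intron profiles, density bins and
## significant-vs-control enrichment.
## ------------------------------------------------------------------

#' Count YCAY motif occurrences in a sequence
#'
#' Pure sliding 4-mer window over `[CT]CA[CT]`; overlapping occurrences
#' are counted. `U` is mapped to `T`; any other non-ACGT character is an
#' error naming the offending offset.
#'
#' @param sequence a single nucleotide string.
#' @return integer occurrence count.
#' @examples
#' count_ycay("TCACCCAT")  # 2
#' count_ycay("TCATCAT")   # 2, overlapping at one base
#' @export
count_ycay <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  s <- chartr("u", "t", chartr("U", "T", toupper(sequence)))
  bad <- regexpr("[^ACGT]", s)[1L]
  if (bad > 0L)
    stop_config("non-ACGTU character '%s' at offset %d",
                substr(s, bad, bad), bad - 1L)
  m <- gregexpr("(?=[CT]CA[CT])", s, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' YCAY motif profile of one transcript
#'
#' Scans spliced exon sequences in transcript orientation (minus-strand
#' genes are reverse-complemented), returning per-exon counts (numbered
#' in transcript order), the exonic total, a tally of sites spanning
#' exon-exon boundaries in the spliced form (excluded from per-exon
#' totals), and the upstream/downstream flanking-intron counts for a
#' designated focus exon.
#'
#' @param gene_model a gene model from [make_fixture()] (fields
#'   `gene_id`, `contig`, `strand`, `exons` 0-based half-open matrix,
#'   optional `focus_exon`, `alt_offset`).
#' @param genome a `toy_genome`.
#' @param focus_exon exon index (genomic order) whose flanking introns
#'   are profiled; defaults to the model's `focus_exon`.
#' @param bins category bin edges passed to [categorize_ycay()].
#' @return list of class `"motif_profile"`: `gene_id`, `exon_counts`,
#'   `exonic_total`, `junction_spanning`, `intron_upstream`,
#'   `intron_downstream` (NA without a focus exon), `gene_body_total`
#'   (unspliced gene span), `category`.
#' @export
profile_transcript <- function(gene_model, genome, focus_exon = NULL,
                               bins = c(20L, 60L)) {
  focus_exon <- focus_exon %||% gene_model$focus_exon
  ex <- gene_model$exons
  n <- nrow(ex)
  seqs <- gene_exon_seqs(gene_model, genome)
  exon_counts <- vapply(seqs, count_ycay, integer(1), USE.NAMES = FALSE)
  spliced <- paste(seqs, collapse = "")
  spanning <- count_ycay(spliced) - sum(exon_counts)
  cs <- genome[[gene_model$contig]]
  body <- subseq0(cs, ex[1L, "start"], ex[n, "end"])
  if (gene_model$strand == "-") body <- revcomp(body)

  up <- dn <- NA_integer_
  if (!is.null(focus_exon) && !is.na(focus_exon)) {
    if (focus_exon < 1L || focus_exon > n)
      stop_config("focus exon %d not in gene model '%s'", focus_exon,
                  gene_model$gene_id)
    intr <- function(i)        # intron after genomic exon i, transcript strand
      if (i < 1L || i >= n) NA_integer_
      else {
        s <- subseq0(cs, ex[i, "end"], ex[i + 1L, "start"])
        if (gene_model$strand == "-") s <- revcomp(s)
        count_ycay(s)
      }
    if (gene_model$strand == "+") {
      up <- intr(focus_exon - 1L); dn <- intr(focus_exon)
    } else {
      up <- intr(focus_exon); dn <- intr(focus_exon - 1L)
    }
  }
  total <- sum(exon_counts)
  structure(list(gene_id = gene_model$gene_id, exon_counts = exon_counts,
                 exonic_total = total, junction_spanning = spanning,
                 intron_upstream = up, intron_downstream = dn,
                 gene_body_total = count_ycay(body),
                 category = categorize_ycay(total, bins)),
            class = "motif_profile")
}

#' Bin a transcript by exonic YCAY density
#'
#' `low` below `bins[1]` sites, `intermediate` from `bins[1]` up to but
#' excluding `bins[2]`, `enriched` at `bins[2]` or more. With the
#' default bins (20, 60): low < 20, intermediate 20-59, enriched >= 60
#' (a count of exactly 60 is assigned to `enriched`).
#'
#' @param exonic_total exonic YCAY count (vectorised).
#' @param bins two increasing non-negative integers (default `c(20, 60)`).
#' @return character vector of categories.
#' @export
categorize_ycay <- function(exonic_total, bins = c(20L, 60L)) {
  stopifnot(length(bins) == 2L, bins[1] < bins[2])
  ifelse(exonic_total < bins[1], "low",
         ifelse(exonic_total < bins[2], "intermediate", "enriched"))
}

#' Compare YCAY density between significant and control transcript sets
#'
#' Proportions of transcripts with exonic YCAY count at or above `cut`
#' in each set, the sample odds ratio, and a two-sided Fisher exact test
#' on the 2x2 table.
#'
#' @param significant,control numeric vectors of exonic YCAY totals (or
#'   lists of `motif_profile`s).
#' @param cut density cut-off (default 20).
#' @return list: `prop_significant`, `prop_control`, `odds_ratio`
#'   (sample OR), `p_value`, `table` (2x2 counts).
#' @export
compare_sets <- function(significant, control, cut = 20L) {
  tot <- function(x) {
    if (is.list(x)) x <- vapply(x, function(p) p$exonic_total, numeric(1))
    x
  }
  s <- tot(significant); ctl <- tot(control)
  if (length(s) == 0L || length(ctl) == 0L)
    stop_config("both transcript sets must be non-empty")
  a <- sum(s >= cut); b <- sum(s < cut)
  c_ <- sum(ctl >= cut); d <- sum(ctl < cut)
  tab <- matrix(c(a, b, c_, d), 2L, 2L,
                dimnames = list(c("atOrAbove", "below"),
                                c("significant", "control")))
  orr <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
  if (a == 0 || d == 0) orr <- if (b == 0 || c_ == 0) 1 else 0
  p <- stats::fisher.test(tab)$p.value
  list(prop_significant = a / length(s), prop_control = c_ / length(ctl),
       odds_ratio = orr, p_value = p, table = tab)
}
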