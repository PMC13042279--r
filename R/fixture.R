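#' Simulation parameters for the bundled toy study
#'
#' Returns the default configuration of the synthetic-data generator. The
#' defaults encode the study conditions the package emulates: a crh-1-like
#' locus whose fourth exon carries one shared splice donor and two
#' alternative 3' splice acceptors 6 nt apart (exon isoforms of 205 and
#' 211 nt, each circularising), one representative locus per linear
#' splicing event class (SE, A3'SS, A5'SS, RI, MXE), several circRNA host
#' genes with genotype-specific abundances, two genotypes (wild-type and a
#' nova-1-like mutant) with five biological replicates each, paired-end
#' 150 nt reads, negative-binomial count dispersion 0.05 and a 10% PCR
#' duplicate fraction.
#'
#' @param seed integer seed; every downstream table is regenerable
#'   bit-identically from it.
#' @param alt_acceptors logical; if `FALSE` the designated exon has a
#'   single acceptor and yields one circRNA isoform.
#' @param alt_offset distance in nt between the two alternative acceptors
#'   (default 6).
#' @param alt_exon_len length in nt of the long (upstream-acceptor) exon
#'   isoform (default 211; the short isoform is `alt_exon_len - alt_offset`).
#' @param n_reps biological replicates per genotype (default 5).
#' @param read_len read length in nt (default 150).
#' @param overhang minimum anchor on each side of a junction seam for a
#'   read to be emitted/counted (default 8 nt).
#' @param dup_fraction expected fraction of junction read pairs that are
#'   re-emitted as byte-identical PCR duplicates (default 0.1).
#' @param phi negative-binomial dispersion of per-sample junction counts
#'   (variance mu + phi * mu^2; default 0.05).
#' @param event_depth mean read-pair depth per linear splicing event per
#'   sample (default 100).
#' @return a list of class `"nova_config"`.
#' @export
fixture_config <- function(seed = 1L, alt_acceptors = TRUE, alt_offset = 6L,
                           alt_exon_len = 211L, n_reps = 5L, read_len = 150L,
                           overhang = 8L, dup_fraction = 0.1, phi = 0.05,
                           event_depth = 100L) {
  if (overhang > read_len / 2)
    stop_config("overhang (%d) may not exceed half the read length (%d)",
                overhang, read_len)
  if (dup_fraction < 0 || dup_fraction >= 1)
    stop_config("dup_fraction must lie in [0, 1)")
  structure(list(
    seed = as.integer(seed), alt_acceptors = alt_acceptors,
    alt_offset = as.integer(alt_offset), alt_exon_len = as.integer(alt_exon_len),
    n_reps = as.integer(n_reps), read_len = as.integer(read_len),
    overhang = as.integer(overhang), dup_fraction = dup_fraction, phi = phi,
    event_depth = event_depth,
    genotypes = c("WT", "nova1")
  ), class = "nova_config")
}

## One gene's construction recipe.  All coordinates 0-based half-open.
gene_recipe <- function(gene_id, strand, exon_lens, intron_lens,
                        exon_ycay = NULL, intron_ycay = NULL,
                        focus_exon = NA_integer_, circ_exons = integer(0)) {
  stopifnot(length(intron_lens) == length(exon_lens) - 1L)
  list(gene_id = gene_id, strand = strand, exon_lens = exon_lens,
       intron_lens = intron_lens,
       exon_ycay = exon_ycay %||% rep(0L, length(exon_lens)),
       intron_ycay = intron_ycay %||% rep(0L, length(intron_lens)),
       focus_exon = focus_exon, circ_exons = circ_exons)
}

default_recipes <- function(config) {
  alt_len <- if (config$alt_acceptors) config$alt_exon_len else config$alt_exon_len
  list(
    ## crh-1-like: 9 exons; exon 4 = focus (alt 3'SS + back-splicing),
    ## planted YCAY geometry: 8 in exon 4 (>= 3 more than any other exon),
    ## 7 / 8 in the flanking introns, 43 exonic total.
    crh1L = gene_recipe("crh1L", "+",
      exon_lens   = c(180L, 200L, 170L, alt_len, 190L, 180L, 170L, 160L, 180L),
      intron_lens = rep(300L, 8L),
      exon_ycay   = c(5L, 5L, 5L, 8L, 5L, 5L, 4L, 3L, 3L),
      intron_ycay = c(0L, 0L, 7L, 8L, 0L, 0L, 0L, 0L),
      focus_exon  = 4L, circ_exons = 4L),
    seG  = gene_recipe("seG", "+", c(200L, 180L, 160L, 180L, 200L), rep(300L, 4L)),
    a5G  = gene_recipe("a5G", "+", c(260L, 200L, 180L), rep(300L, 2L)),
    riG  = gene_recipe("riG", "+", c(200L, 200L), 300L),
    mxeG = gene_recipe("mxeG", "+", c(200L, 170L, 170L, 200L), rep(300L, 3L)),
    minusG = gene_recipe("minusG", "-", c(180L, 200L, 180L), rep(300L, 2L),
                         circ_exons = 2L),
    cirA = gene_recipe("cirA", "+", c(180L, 220L, 180L), rep(300L, 2L),
                       circ_exons = 2L),
    cirB = gene_recipe("cirB", "+", c(180L, 220L, 180L), rep(300L, 2L),
                       circ_exons = 2L),
    cirC = gene_recipe("cirC", "+", c(180L, 220L, 180L), rep(300L, 2L),
                       circ_exons = 2L),
    cirD = gene_recipe("cirD", "+", c(180L, 220L, 180L), rep(300L, 2L),
                       circ_exons = 2L)
  )
}

## WT mean unique BSJ read pairs per sample and mutant log2 fold change.
default_circ_truth <- function() {
  data.frame(
    circ_id = c("circ_crh1L_long", "circ_crh1L_short", "circ_cirA_1",
                "circ_cirB_1", "circ_cirC_1", "circ_cirD_1", "circ_minusG_1"),
    mean_wt = c(60, 50, 40, 80, 30, 1, 25),
    log2fc  = c(-1, 0, 1, -1, 0, 0, 0),
    stringsAsFactors = FALSE)
}

## Per-event true PSI by genotype (WT, mutant).  The A3'SS and SE events
## carry genotype effects (reduced inclusion in the mutant, matching the
## WT-minus-mutant orientation of dPSI); the rest are null.
default_event_truth <- function() {
  data.frame(
    event_id = c("A3SS_crh1L", "SE_seG", "A5SS_a5G", "RI_riG", "MXE_mxeG"),
    psi_wt  = c(0.8, 0.7, 0.5, 0.3, 0.6),
    psi_mut = c(0.5, 0.4, 0.5, 0.3, 0.6),
    stringsAsFactors = FALSE)
}

build_gene <- function(recipe, config) {
  nex <- length(recipe$exon_lens)
  ## Asymmetric boundary guards (exon GG...CC, intron TT...AA) prevent
  ## both YCAY windows spanning any boundary and micro-homology around
  ## splice seams, so back-splice breakpoints are sequence-unique.
  mk_piece <- function(len, ycay, kind) {
    s <- strip_ycay(random_dna(len))
    g <- if (kind == "exon") c("GG", "CC") else c("TT", "AA")
    substr(s, 1L, 2L) <- g[1]
    substr(s, len - 1L, len) <- g[2]
    s <- strip_ycay(s)
    plant_ycay(s, ycay)
  }
  exon_seqs <- mapply(mk_piece, recipe$exon_lens, recipe$exon_ycay,
                      MoreArgs = list(kind = "exon"), SIMPLIFY = TRUE)
  intron_seqs <- if (nex > 1L)
    mapply(mk_piece, recipe$intron_lens, recipe$intron_ycay,
           MoreArgs = list(kind = "intron"), SIMPLIFY = TRUE)
  else character(0)
  if (!is.na(recipe$focus_exon) && isTRUE(config$alt_acceptors)) {
    ## guard the short-acceptor boundary inside the focus exon
    fe <- recipe$focus_exon
    off <- config$alt_offset
    s <- exon_seqs[fe]
    substr(s, off + 1L, off + 2L) <- "GG"
    exon_seqs[fe] <- strip_ycay(s)
    exon_seqs[fe] <- if (recipe$exon_ycay[fe] > 0)
      plant_ycay(substr_blank_replant(exon_seqs[fe]), recipe$exon_ycay[fe])
    else exon_seqs[fe]
  }
  list(exon_seqs = exon_seqs, intron_seqs = intron_seqs)
}

## re-strip planted motifs so plant_ycay() can re-plant an exact count
substr_blank_replant <- function(s) strip_ycay(s)

#' Build the bundled toy genome, gene models and circRNA loci
#'
#' Deterministically (for a fixed seed) constructs a single-contig toy
#' genome containing a crh-1-like locus plus representative loci for the
#' five linear splicing event classes and several circRNA host genes, and
#' returns gene models, circRNA loci with ground-truth abundances, and
#' splicing-event definitions with ground-truth PSI.
#'
#' @param config a [fixture_config()] list.
#' @return an object of class `"nova_fixture"`: a list with elements
#'   `genome` (named character vector of contigs), `genes` (list of gene
#'   models), `circs` (data.frame of circRNA loci: `circ_id`, `gene_id`,
#'   `contig`, `start`, `end` (0-based half-open), `strand`, `length`,
#'   truth columns `mean_wt`, `log2fc`), `events` (list of splicing event
#'   definitions) and `config`.
#' @examples
#' fx <- make_fixture(fixture_config(seed = 7))
#' subset(fx$circs, gene_id == "crh1L")   # two isoforms, 6 nt apart
#' @export
make_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "nova_config"))
  withr::with_seed(config$seed, make_fixture_impl(config))
}

make_fixture_impl <- function(config) {
  recipes <- default_recipes(config)
  contig <- "toyI"
  pieces <- character(0)
  offset <- 0L
  pad <- function(n) strip_ycay(random_dna(n))
  genes <- list()

  for (r in recipes) {
    filler <- pad(500L)
    pieces <- c(pieces, filler); offset <- offset + 500L
    built <- build_gene(r, config)
    nex <- length(r$exon_lens)
    starts <- integer(nex); ends <- integer(nex)
    gene_pieces <- character(0)
    pos <- offset
    for (i in seq_len(nex)) {
      starts[i] <- pos
      ends[i] <- pos + r$exon_lens[i]
      gene_pieces <- c(gene_pieces, built$exon_seqs[i])
      pos <- ends[i]
      if (i < nex) {
        gene_pieces <- c(gene_pieces, built$intron_seqs[i])
        pos <- pos + r$intron_lens[i]
      }
    }
    pieces <- c(pieces, gene_pieces)
    offset <- pos
    gm <- structure(list(
      gene_id = r$gene_id, contig = contig, strand = r$strand,
      exons = cbind(start = starts, end = ends),
      focus_exon = r$focus_exon,
      alt_offset = if (!is.na(r$focus_exon) && config$alt_acceptors)
        config$alt_offset else NA_integer_,
      circ_exons = r$circ_exons), class = "gene_model")
    genes[[r$gene_id]] <- gm
  }
  pieces <- c(pieces, pad(500L))
  genome <- structure(stats::setNames(paste(pieces, collapse = ""), contig),
                      class = "toy_genome")

  circs <- fixture_circs(genes, config)
  truth <- default_circ_truth()
  circs <- merge(circs, truth, by = "circ_id", all.x = TRUE, sort = FALSE)
  circs$mean_wt[is.na(circs$mean_wt)] <- 30
  circs$log2fc[is.na(circs$log2fc)] <- 0
  circs <- circs[order(circs$circ_id), , drop = FALSE]
  rownames(circs) <- NULL

  events <- fixture_events(genes, config)

  structure(list(genome = genome, genes = genes, circs = circs,
                 events = events, config = config),
            class = "nova_fixture")
}

fixture_circs <- function(genes, config) {
  rows <- list()
  for (gm in genes) {
    for (ci in gm$circ_exons) {
      st <- gm$exons[ci, "start"]; en <- gm$exons[ci, "end"]
      if (!is.na(gm$focus_exon) && ci == gm$focus_exon &&
          config$alt_acceptors) {
        ## one shared donor (exon end), two acceptors `alt_offset` nt apart
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = paste0("circ_", gm$gene_id, "_long"), gene_id = gm$gene_id,
          contig = gm$contig, start = st, end = en, strand = gm$strand,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = paste0("circ_", gm$gene_id, "_short"), gene_id = gm$gene_id,
          contig = gm$contig, start = st + config$alt_offset, end = en,
          strand = gm$strand, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          circ_id = paste0("circ_", gm$gene_id, "_1"), gene_id = gm$gene_id,
          contig = gm$contig, start = st, end = en, strand = gm$strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$length <- out$end - out$start
  out
}

splice_event <- function(event_id, type, gene_id, contig, strand,
                         inclusion, skipping, psi_wt, psi_mut) {
  structure(list(event_id = event_id, type = type, gene_id = gene_id,
                 contig = contig, strand = strand, inclusion = inclusion,
                 skipping = skipping, psi_wt = psi_wt, psi_mut = psi_mut),
            class = "splice_event")
}

fixture_events <- function(genes, config) {
  tr <- default_event_truth()
  psi <- function(id) unlist(tr[tr$event_id == id, c("psi_wt", "psi_mut")])
  ev <- list()
  jx <- function(left_end, right_start)
    c(left_end = unname(left_end), right_start = unname(right_start))
  g <- genes$crh1L
  if (!is.null(g) && isTRUE(config$alt_acceptors)) {
    d <- g$exons[3L, "end"]
    a_long <- g$exons[4L, "start"]; a_short <- a_long + config$alt_offset
    p <- psi("A3SS_crh1L")
    ev$A3SS_crh1L <- splice_event("A3SS_crh1L", "A3SS", "crh1L", g$contig, "+",
      inclusion = list(jx(d, a_long)), skipping = list(jx(d, a_short)),
      psi_wt = p[1], psi_mut = p[2])
  }
  g <- genes$seG
  if (!is.null(g)) {
    p <- psi("SE_seG")
    ev$SE_seG <- splice_event("SE_seG", "SE", "seG", g$contig, "+",
      inclusion = list(jx(g$exons[2, "end"], g$exons[3, "start"]),
                       jx(g$exons[3, "end"], g$exons[4, "start"])),
      skipping  = list(jx(g$exons[2, "end"], g$exons[4, "start"])),
      psi_wt = p[1], psi_mut = p[2])
  }
  g <- genes$a5G
  if (!is.null(g)) {
    p <- psi("A5SS_a5G")
    d_long <- g$exons[1, "end"]; d_short <- d_long - 12L
    ev$A5SS_a5G <- splice_event("A5SS_a5G", "A5SS", "a5G", g$contig, "+",
      inclusion = list(jx(d_long, g$exons[2, "start"])),
      skipping  = list(jx(d_short, g$exons[2, "start"])),
      psi_wt = p[1], psi_mut = p[2])
  }
  g <- genes$riG
  if (!is.null(g)) {
    p <- psi("RI_riG")
    ## retained intron: contiguous genomic windows across the two
    ## exon/intron boundaries (left_end == right_start marks contiguity)
    ev$RI_riG <- splice_event("RI_riG", "RI", "riG", g$contig, "+",
      inclusion = list(jx(g$exons[1, "end"], g$exons[1, "end"]),
                       jx(g$exons[2, "start"], g$exons[2, "start"])),
      skipping  = list(jx(g$exons[1, "end"], g$exons[2, "start"])),
      psi_wt = p[1], psi_mut = p[2])
  }
  g <- genes$mxeG
  if (!is.null(g)) {
    p <- psi("MXE_mxeG")
    ev$MXE_mxeG <- splice_event("MXE_mxeG", "MXE", "mxeG", g$contig, "+",
      inclusion = list(jx(g$exons[1, "end"], g$exons[2, "start"]),
                       jx(g$exons[2, "end"], g$exons[4, "start"])),
      skipping  = list(jx(g$exons[1, "end"], g$exons[3, "start"]),
                       jx(g$exons[3, "end"], g$exons[4, "start"])),
      psi_wt = p[1], psi_mut = p[2])
  }
  ev
}

#' @export
print.nova_fixture <- function(x, ...) {
  cat("nova_fixture: ", sum(nchar(x$genome)), " bp over ",
      length(x$genome), " contig(s); ", length(x$genes), " genes, ",
      nrow(x$circs), " circRNA loci, ", length(x$events),
      " splicing events (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Extract the spliced (transcript-orientation) exon sequences of a gene
#'
#' @param gene_model a gene model from [make_fixture()].
#' @param genome a `toy_genome` (named character vector of contigs).
#' @param use_alt for a gene with an alternative acceptor on its focus
#'   exon, `"long"` (default) or `"short"` selects the exon isoform.
#' @return character vector of exon sequences in transcript order
#'   (minus-strand genes are reverse-complemented and reversed).
#' @export
gene_exon_seqs <- function(gene_model, genome, use_alt = c("long", "short")) {
  use_alt <- match.arg(use_alt)
  cs <- genome[[gene_model$contig]]
  ex <- gene_model$exons
  if (!is.na(gene_model$alt_offset) && use_alt == "short")
    ex[gene_model$focus_exon, "start"] <-
      ex[gene_model$focus_exon, "start"] + gene_model$alt_offset
  seqs <- vapply(seq_len(nrow(ex)),
                 function(i) subseq0(cs, ex[i, "start"], ex[i, "end"]),
                 character(1))
  if (gene_model$strand == "-") seqs <- rev(revcomp(seqs))
  seqs
}

#' Write fixture files (FASTA, GFF3, BED6)
#'
#' Emits `genome.fa`, `genes.gff3` (1-based closed coordinates) and
#' `circs.bed` (0-based half-open) into `dir`. Byte-identical for a fixed
#' fixture.
#'
#' @param fixture a `nova_fixture`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  bed <- file.path(dir, "circs.bed")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(fixture$genome)), fa)
  gr_list <- lapply(fixture$genes, function(gm) {
    n <- nrow(gm$exons)
    GenomicRanges::GRanges(
      seqnames = gm$contig,
      ranges = IRanges::IRanges(start = gm$exons[, "start"] + 1L,
                                end = gm$exons[, "end"]),
      strand = gm$strand, type = "exon",
      ID = paste0(gm$gene_id, ".e", seq_len(n)),
      Parent = gm$gene_id)
  })
  gr <- suppressWarnings(do.call(c, unname(gr_list)))
  rtracklayer::export(gr, gff, format = "gff3")
  cb <- GenomicRanges::GRanges(
    seqnames = fixture$circs$contig,
    ranges = IRanges::IRanges(start = fixture$circs$start + 1L,
                              end = fixture$circs$end),
    strand = fixture$circs$strand,
    name = fixture$circs$circ_id, score = 0L)
  rtracklayer::export(cb, bed, format = "BED")
  invisible(c(fa, gff, bed))
}
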