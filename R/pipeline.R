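## ------------------------------------------------------------------
## End-to-end orchestration on synthetic data: fixture -> reads ->
## circRNA calling/counting/filtering -> NB QL differential expression
## -> PSI testing -> YCAY profiling -> gene-level overlap, with a
## deterministic manifest of content hashes.
## ------------------------------------------------------------------

#' Pipeline run configuration
#'
#' Thresholds default to the study's values: junction-read filter 12,
#' |log2FC| 0.5 at alpha 0.05 for circRNA DE (gating on raw P), FDR
#' 0.05 and |dPSI| 0.2 for splicing, YCAY bins at 20/60.
#'
#' @param seed integer seed driving fixture and read simulation.
#' @param min_junction_reads pooled unique junction-read filter.
#' @param lfc,alpha DE thresholds.
#' @param use DE gate: `"p"` (default) or `"fdr"`.
#' @param fdr,dpsi splicing significance thresholds.
#' @param ycay_bins density bins for [categorize_ycay()].
#' @param ycay_cut density cut for [compare_sets()].
#' @param n_reps,dup_fraction,phi,event_depth forwarded to the
#'   simulators (defaults from [fixture_config()]).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, min_junction_reads = 12L, lfc = 0.5,
                       alpha = 0.05, use = "p", fdr = 0.05, dpsi = 0.2,
                       ycay_bins = c(20L, 60L), ycay_cut = 20L,
                       n_reps = 5L, dup_fraction = 0.1, phi = 0.05,
                       event_depth = 100L) {
  stopifnot(min_junction_reads >= 0, lfc > 0, alpha > 0, fdr > 0, dpsi > 0)
  structure(as.list(environment()), class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in study order -- quantify circRNAs, test
#' differential expression, quantify and test linear splicing, profile
#' YCAY motifs, and overlap the two regulatory programs -- writing every
#' result table into `outdir` plus a manifest of MD5 content hashes.
#' Reruns with the same configuration produce hash-identical outputs.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @return (invisibly) a list with the in-memory stage results and the
#'   `manifest` data.frame (`file`, `md5`).
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(stage, ...) {
    message(sprintf("[novapipe %6.1fs] %s %s",
                    proc.time()[["elapsed"]] - t0, stage,
                    paste0(..., collapse = "")))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  log_stage("fixture", "building toy genome (seed ", config$seed, ")")
  fx <- make_fixture(fixture_config(
    seed = config$seed, n_reps = config$n_reps,
    dup_fraction = config$dup_fraction, phi = config$phi,
    event_depth = config$event_depth))
  write_fixture(fx, outdir)

  log_stage("simulate", "emitting junction read pairs")
  sim <- simulate_reads(fx)
  groups <- sim$truth$genotype

  log_stage("circ_quant", "split-read BSJ calling")
  loci <- call_bsj(sim$samples, fx$genome)
  loci$circ_id <- sprintf("bsj_%s_%d_%d%s", loci$contig, loci$start,
                          loci$end, loci$strand)
  scafs <- lapply(seq_len(nrow(loci)), function(i)
    build_scaffold(loci[i, ], fx$genome))
  counts_long <- count_junction_reads(scafs, sim$samples,
                                      min_overhang = fx$config$overhang)
  cmat <- junction_count_matrix(counts_long, "unique")
  kept <- filter_circ(cmat, config$min_junction_reads)
  write_tsv(counts_long, file.path(outdir, "circ_counts.tsv"))
  removed <- attr(kept, "removed")
  writeLines(c(sprintf("# min_junction_reads=%d scope=pooled",
                       config$min_junction_reads),
               if (length(removed)) paste0("removed\t", removed)
               else "removed\t(none)"),
             file.path(outdir, "circ_filter.log"))

  log_stage("diff_expression", sprintf("%d circRNAs after filter", nrow(kept)))
  de <- fit_nb_test(kept, groups[colnames(kept)])
  de <- classify_de(de, config$lfc, config$alpha, use = config$use)
  write_tsv(de, file.path(outdir, "circ_de.tsv"))

  log_stage("splice_psi", "counting event junction reads")
  ev_counts <- do.call(rbind, lapply(fx$events, count_event_reads,
                                     reads = sim$samples,
                                     genome = fx$genome,
                                     min_overhang = fx$config$overhang,
                                     flank = fx$config$read_len))
  psi <- psi_test_table(ev_counts, groups, events = fx$events,
                        read_len = fx$config$read_len,
                        overhang = fx$config$overhang)
  flt <- filter_events(psi, fdr = config$fdr, dpsi = config$dpsi)
  write_tsv(psi, file.path(outdir, "splice_results.tsv"))
  write_tsv(flt$significant, file.path(outdir, "splice_significant.tsv"))
  write_tsv(flt$summary, file.path(outdir, "splice_summary.tsv"))

  log_stage("motif_ycay", "profiling transcripts")
  profs <- lapply(fx$genes, profile_transcript, genome = fx$genome,
                  bins = config$ycay_bins)
  prof_df <- do.call(rbind, lapply(profs, function(p) data.frame(
    gene_id = p$gene_id,
    exon_counts = paste(p$exon_counts, collapse = ","),
    exonic_total = p$exonic_total,
    junction_spanning = p$junction_spanning,
    intron_upstream = p$intron_upstream,
    intron_downstream = p$intron_downstream,
    category = p$category, stringsAsFactors = FALSE)))
  rownames(prof_df) <- NULL
  write_tsv(prof_df, file.path(outdir, "motif_profiles.tsv"))

  log_stage("integration", "gene-level overlap")
  ## map called loci back to annotated circles by coordinates
  key_called <- paste(loci$contig, loci$start, loci$end, loci$strand)
  key_anno <- paste(fx$circs$contig, fx$circs$start, fx$circs$end,
                    fx$circs$strand)
  gene_map <- stats::setNames(fx$circs$gene_id[match(key_called, key_anno)],
                              loci$circ_id)
  gene_map <- gene_map[!is.na(gene_map)]
  ov <- overlap_sets(de, flt$significant, gene_map)
  write_tsv(ov$venn, file.path(outdir, "overlap_venn.tsv"))
  write_tsv(ov$records, file.path(outdir, "overlap_records.tsv"))

  files <- sort(setdiff(list.files(outdir), "manifest.tsv"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  manifest <- rbind(
    data.frame(file = "#seed", md5 = as.character(config$seed),
               stringsAsFactors = FALSE), manifest)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  log_stage("done", sprintf("%d output files", nrow(manifest) - 1L))

  invisible(list(fixture = fx, sim = sim, loci = loci, counts = cmat,
                 filtered = kept, de = de, psi = psi,
                 significant_events = flt, profiles = profs, overlap = ov,
                 manifest = manifest))
}

#' Run the bundled demonstration end-to-end
#'
#' Builds the crh-1-like fixture and runs every stage with the default
#' thresholds.
#'
#' @param outdir output directory.
#' @param seed integer seed (default 1).
#' @return see [run_pipeline()].
#' @export
demo_run <- function(outdir, seed = 1L) {
  run_pipeline(run_config(seed = seed), outdir)
}
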