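## ------------------------------------------------------------------
## Gene-level overlap of circRNA differential expression and linear
## splicing regulation (the Venn of the two regulatory programs).
## ------------------------------------------------------------------

#' Overlap differentially expressed circRNAs with significant splicing
#' events at the host-gene level
#'
#' @param de_circs data.frame with at least `feature` (circ id) and
#'   `call` columns (from [classify_de()]); only `up`/`down` calls
#'   enter the overlap.
#' @param sig_events data.frame with `event_id`, `gene_id`, `type` and
#'   `IncLevelDifference` columns (from [filter_events()]).
#' @param gene_map named character vector mapping circ ids to host gene
#'   ids. CircRNAs without a mapping are warned about and treated as
#'   circ-only.
#' @return list with `venn` (data.frame: `circ_only`, `shared`,
#'   `splice_only` gene counts) and `records` (one row per shared gene:
#'   `gene_id`, `circ_ids`, `circ_calls`, `event_ids`, `event_types`,
#'   `event_directions`, `class`), both invariant to input order.
#' @export
overlap_sets <- function(de_circs, sig_events, gene_map) {
  de <- de_circs[de_circs$call %in% c("up", "down"), , drop = FALSE]
  mapped <- de$feature %in% names(gene_map)
  if (any(!mapped))
    warning(sprintf("%d circRNA(s) without host-gene mapping treated as circ-only: %s",
                    sum(!mapped), paste(de$feature[!mapped], collapse = ", ")))
  de$gene_id <- ifelse(mapped, unname(gene_map[de$feature]),
                       paste0("unmapped:", de$feature))
  circ_genes <- sort(unique(de$gene_id))
  splice_genes <- sort(unique(sig_events$gene_id))
  shared <- intersect(circ_genes, splice_genes)

  records <- do.call(rbind, lapply(shared, function(g) {
    dc <- de[de$gene_id == g, , drop = FALSE]
    dc <- dc[order(dc$feature), , drop = FALSE]
    se <- sig_events[sig_events$gene_id == g, , drop = FALSE]
    se <- se[order(se$event_id), , drop = FALSE]
    dir <- ifelse(se$IncLevelDifference > 0, "lowPSI.mut", "highPSI.mut")
    data.frame(gene_id = g,
               circ_ids = paste(dc$feature, collapse = ";"),
               circ_calls = paste(dc$call, collapse = ";"),
               event_ids = paste(se$event_id, collapse = ";"),
               event_types = paste(se$type, collapse = ";"),
               event_directions = paste(dir, collapse = ";"),
               class = paste0(paste(sort(unique(dc$call)), collapse = "/"),
                              "-circ + ",
                              paste(sort(unique(paste0(se$type, "-", dir))),
                                    collapse = "+")),
               stringsAsFactors = FALSE)
  }))
  if (is.null(records))
    records <- data.frame(gene_id = character(0), circ_ids = character(0),
                          circ_calls = character(0), event_ids = character(0),
                          event_types = character(0),
                          event_directions = character(0),
                          class = character(0), stringsAsFactors = FALSE)
  venn <- data.frame(circ_only = length(setdiff(circ_genes, shared)),
                     shared = length(shared),
                     splice_only = length(setdiff(splice_genes, shared)))
  list(venn = venn, records = records)
}
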