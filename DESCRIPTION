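Package: circnova
Title: CircRNA Back-Splicing and Alternative Splicing Analysis for
    NOVA-Family RBP Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale analysis toolkit for studying how NOVA-family
    RNA-binding proteins shape circular RNA (circRNA) expression and
    linear alternative splicing, modelled on a C. elegans nova-1 mutant
    versus wild-type design. Provides a ground-truth synthetic-data
    generator (toy genome, gene models with alternative 3' splice
    acceptors, back-splice junction reads, survival and qPCR tables);
    back-splice junction scaffold construction, split-read circRNA
    calling, duplicate-aware junction-read counting and abundance
    filtering; TMM-style normalisation with a negative-binomial
    quasi-likelihood F-test for differential circRNA expression;
    percent-spliced-in (PSI) quantification of the five linear splicing
    event classes with a replicate-aware beta-binomial likelihood-ratio
    test; YCAY motif density profiling and enrichment; gene-level
    overlap of circRNA and splicing regulation; and phenotype
    statistics (2^-ddCt qPCR quantification, Kaplan-Meier/log-rank
    lifespan comparison, heat-shock viability tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    survival,
    limma,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
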