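---
title: "circnova: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circnova: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circnova)
```

This vignette is the package's own account of its science: what each
stage models, which parameters matter and why their defaults were
chosen, what the synthetic generator does and does not emulate, and the
numerical decisions taken where the design was genuinely open.

## The biological setting

Back-splicing joins a downstream splice donor (SD) to an upstream
splice acceptor (SA), producing a covalently closed circular RNA whose
only distinguishing sequence feature is the back-splice junction (BSJ).
NOVA-family RNA-binding proteins bind YCAY tetranucleotides (Y = C or
T) and regulate both linear alternative splicing and, in some systems,
back-splicing. The analysis this package implements compares a
NOVA-deficient mutant against wild-type across four read-outs: circRNA
abundance, linear splicing (PSI), YCAY motif density of the regulated
transcripts, and organismal phenotypes (lifespan, heat-shock recovery,
qPCR validation). The centrepiece locus is a crh-1-like gene whose
fourth exon carries one shared SD and two alternative 3' SAs six
nucleotides apart, so the same exon yields 211-nt and 205-nt isoforms
and, by back-splicing, two circRNA isoforms differing by exactly 6 nt.

## The synthetic-data generator

`make_fixture()` and `simulate_reads()` are first-class, tested code:
they define the study conditions under which every downstream claim is
verified.

**What it emulates.** Two genotypes x five biological replicates of
paired-end 150-nt reads; per-circRNA junction-read counts drawn
negative-binomially (variance mu + phi mu^2, phi = 0.05, the common
scale of bulk RNA-seq biological replication); genotype effects as
log2 fold changes on circRNA means and as PSI shifts on splicing
events; PCR duplicates as byte-identical re-emissions of an existing
pair at a 10% expected fraction, matching coordinate-based duplicate
marking; censored lifespans; and qPCR Ct tables with per-well Gaussian
noise.

**What it deliberately does not emulate.** Sequencing errors and
quality variation, whole-transcript shotgun coverage (reads are emitted
only over junction-informative windows), polymerase stutter, and
genome-scale transcriptome complexity. Consequently, passing tests
demonstrate correctness of the quantification and inference machinery
under an exact observation model -- they do not demonstrate robustness
to alignment ambiguity or base-call error, which real pipelines buy
from dedicated aligners.

**Read geometry.** Junction reads are drawn uniformly over the distinct
(start, mate-start) placements that leave at least the configured
overhang (8 nt) on each side of the seam, *without replacement*, so the
unique (deduplicated) count per feature equals the drawn
negative-binomial count exactly. This makes "counts equal truth with
zero tolerance" a meaningful test rather than a statistical statement.

**Sequence construction.** Exons and introns carry asymmetric 2-nt
boundary guards (exon `GG...CC`, intron `TT...AA`). These serve two
purposes: no YCAY window can span any boundary (so planted motif counts
are exact), and no micro-homology exists around splice seams (so a
back-splice breakpoint is sequence-unique and split-read calling can
recover coordinates exactly). Where micro-homology does make several
breakpoints consistent, the caller deterministically takes the maximal
donor-side extension. The crh-1-like gene carries a planted YCAY
geometry -- 8 sites in the focus exon (at least 3 more than any other
exon), 7 and 8 in its flanking introns, 43 exonic sites in total -- as
a synthetic stand-in for the annotated reference locus, usable by the
same profiling code that would run on real FASTA/GFF3 input.

## circRNA quantification

The 200-nt junction scaffold places the seam centrally: 100 nt of the
circle's 3' end followed by 100 nt of its 5' start, reverse-complemented
for minus-strand circles, tiling the circle circularly when it is
shorter than 100 nt per side. Symmetric seam placement maximises the
detectable overhang on both sides; the layout within the stated total
length was an open choice and is pinned by tests.

`call_bsj()` anchors the first and last k-mers (k = 20) of each read
(both orientations) in an exact k-mer index of the genome; anchors in
inverted order on one contig define a candidate back-splice, whose
breakpoint is refined by maximal exact extension. Reads whose anchors
occur at more than `max_hits` positions are skipped and tallied.
Candidate loci need `min_support = 2` supporting reads by default.

`count_junction_reads()` assigns pairs to scaffolds by exact substring
matching of both mates in both orientations; a pair supports a junction
when either mate spans the seam with >= 8 nt on each side. Duplicates
are collapsed on the (scaffold, offset, mate-offset) tuple. Pairs
matching several scaffolds are dropped and tallied -- multi-mapping
evidence is not divided.

The abundance filter removes circRNAs with pooled unique junction reads
below 12. *Pooled* across samples is the default reading: per-sample
filtering at five replicates of desk-scale depth would discard most
features, and pooled filtering matches common post-hoc practice for
circRNA callers; `scope = "per_sample"` is available.

## Differential expression

`normalize_tmm()` computes trimmed-mean-of-log-ratio scaling factors
(30% two-sided trim on M, 5% on abundance; reference column closest to
the mean log library size; factors centred to geometric mean 1).

`fit_nb_test()` is a compact quasi-likelihood NB pipeline:

1. per-feature dispersion by Cox-Reid-adjusted profile likelihood under
   the two-group model with effective-library-size offsets;
2. shrinkage toward the mean-dispersion trend (lowess against abundance
   when there are >= 50 features, otherwise the mean) with
   `prior_df = 10` -- small-replicate stability without porting any
   external implementation;
3. the genotype contrast as a deviance-drop F statistic whose
   denominator is the residual deviance scale squeezed by
   empirical-Bayes moment matching (`limma::squeezeVar`), with
   denominator df equal to residual plus prior df.

With 2,000 simulated null features (mu = 100, phi = 0.05, 5 vs 5) the
test's measured type-I error at nominal 0.05 is ~0.056, and the median
estimated log2FC at a true effect of 2 is within 0.01 of truth (both
recomputed in the test suite at these problem sizes). A prior count of
0.125 per group mean keeps log2FC finite at zeros.

**Sign convention.** log2FC = log2(mutant / wild-type), so "up" means
higher in the mutant; `paper_sign = TRUE` flips to the opposite
orientation used by reports that phrase the contrast wild-type-first.
Classification gates on raw P by default with FDR also emitted
(`use = "fdr"` switches the gate), since common threshold wording in this literature
mixes both; both modes are provided rather than adjudicated.

## Splicing PSI and the beta-binomial test

Each of the five event classes is reduced to its defining junction set:
SE (two inclusion junctions, one skipping), A3'SS/A5'SS (one each,
sharing the non-alternative site), RI (two contiguous exon-intron
boundary windows versus the spliced junction), MXE (two junctions per
exon). Effective form lengths count distinct supporting read positions:
`read_len - 2 * overhang + 1` per junction (135 at the defaults);
`mode = "jcec"` additionally credits alternative-region body positions.
The junction-count mode is the default because the generator emits
junction-informative reads only, so body evidence does not exist under
the study conditions.

PSI = (I/l_I) / (I/l_I + S/l_S). The two-group test models per-sample
inclusion counts as beta-binomial with a shared overdispersion,
profiled by maximum likelihood jointly with the proportions; the
likelihood ratio for one-versus-two proportions is referred to
F(1, n - 2) rather than the asymptotic chi-squared(1). The F reference
is the package's small-sample calibration choice: at 5 vs 5 replicates
the chi-squared reference measured ~0.07 type-I at nominal 0.05 while
F(1, 8) measured ~0.044, inside the intended band; `null_dist =
"chisq"` restores the asymptotic reference. A pure binomial LRT is
available via `rho = 0` and is verified against a closed-form oracle.

dPSI is wild-type minus mutant, so loss of an inclusion form in the
mutant is positive. Significance requires FDR <= 0.05 *and*
|dPSI| >= 0.2 (at least a 20% splicing change).

## YCAY motifs

Occurrences of `[CT]CA[CT]` are counted by a pure sliding window with
overlaps -- the simplest well-defined rule, pinned by an exhaustive
window oracle in the tests. Scanning is always in transcript
orientation (YCAY is not reverse-complement symmetric; its RC is RTGR).
Per-exon counts use spliced exon sequences; sites spanning exon-exon
boundaries in the spliced form are tallied separately and excluded from
per-exon totals; the unspliced gene-body total is also reported so any
counting convention can be checked against a reference annotation.
Density bins are low < 20, intermediate 20-59, enriched >= 60: the
conventional binning leaves exactly 60 unassigned, and this package
assigns it to enriched (configurable). Set enrichment uses the
proportion at/above a cut of 20 with a two-sided Fisher exact test.

## Overlap and phenotype statistics

Overlap between circRNA and splicing regulation is defined at the host
gene level (not coordinate intersection), matching the gene-level Venn
this analysis feeds. For phenotypes: 2^-ddCt normalises each target Ct
to a housekeeping gene (the housekeeping id is a configuration value,
never hard-coded) and then to the wild-type mean dCt; lifespans are
compared by the Mantel-Cox log-rank test with Kaplan-Meier curves, and
"mean lifespan" is reported both as the KM-restricted mean (truncated at
the last observed death; the headline percent change uses this) and as
the arithmetic mean of uncensored deaths, because the phrase is
ambiguous in common usage. The survival simulator defaults encode the
study conditions -- 150 animals per group, wild-type Weibull scale 17
days and shape 4 (a realistic ~28% CV for worm lifespan), mutant hazard
ratio 1.1475^-4 so the mutant restricted mean is ~14.75% longer.
Heat-shock viability uses an equal-variance unpaired two-tailed t-test
by default because replicate counts are tiny (three); Welch is a flag.

## Numerical choices and degenerate inputs

* All intervals are 0-based half-open internally; GFF3 output is
  1-based closed, BED stays 0-based half-open.
* Ties and boundaries: a breakpoint ambiguity resolves to the maximal
  donor-side split; a density of exactly 60 is enriched; pooled
  junction reads of exactly 12 survive the filter; |log2FC| of exactly
  0.5 does not pass the strict DE gate.
* Degenerate inputs: all-zero features are excluded and tallied;
  events with I + S = 0 in a sample drop that sample; all-inclusion or
  all-skipping events return P = 1; a survival group with no deaths is
  an explicit error; a missing housekeeping Ct names the sample.
* Every simulator seeds all randomness through one integer and is
  bit-reproducible; the pipeline writes an MD5 manifest and reruns are
  hash-identical.

## Problem sizes

The bundled fixture is a single ~21-kb contig with ten genes, seven
circRNA loci and five splicing events; default simulations emit on the
order of 8,000 read pairs across ten samples, which the test suite and
the demonstration pipeline process in seconds to a couple of minutes.
Calibration suites use 2,000 null NB features, 1,000 null splicing
events and 500 survival replications -- sizes chosen so each Monte-Carlo
band is tight enough to be informative while the whole suite stays
fast.

## Known limitations

Exact matching means zero tolerance to sequencing error; the NB and
beta-binomial tests are compact reimplementations whose behaviour is
verified by simulation and cross-checks, not ports of any established
tool's full machinery (no abundance-dependent QL prior df trend, no
paired designs, no covariates); event definitions are annotation-driven
(no novel-junction discovery); and the overlap stage is set arithmetic,
not a colocalisation statistic.
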