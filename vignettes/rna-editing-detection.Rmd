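---
title: "Detecting A-to-I RNA editing as RNA-DNA differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA editing as RNA-DNA differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaedit)
```

## The problem

Adenosine deaminases acting on RNA (ADAR enzymes) convert adenosine to
inosine in double-stranded RNA. Because the cellular machinery — and the
reverse transcriptase used in sequencing — reads inosine as guanosine,
editing events surface in RNA-seq data as A>G mismatches against the
genome (T>C in genomic coordinates for genes transcribed from the minus
strand). The difficulty is that the same mismatch signature is produced by
germline variation, sequencing error, and alignment artifacts, all of
which are orders of magnitude more common than true editing at most sites.

`rnaedit` implements the conservative "RNA-DNA difference" (RDD) strategy:
call candidate single-nucleotide variants from RNA-seq pileups under
strict evidence rules, remove positions prone to alignment artifacts,
resolve the transcript strand through gene annotations, and finally demand
that deep whole-genome DNA sequencing of the same subject shows *zero*
reads supporting the variant at high coverage. What survives is, with high
confidence, a post-transcriptional event. Canonical A-to-I sites are the
sense-strand A>G class; other classes are retained but flagged
non-canonical.

## The filter cascade and its parameters

All thresholds live in `rdd_config()` and have the following defaults,
chosen to match stringent practice for short-read editing detection:

| parameter | default | meaning |
|---|---|---|
| `read_min_frac`, `read_min_qual` | 0.70, Q23 | keep a read only if >= 70% of its cycles reach Q23; reads must also be uniquely mapped |
| `min_cov` | 10 | minimum total filtered-read depth at a callable site |
| `min_alt_reads` | 2 | minimum "unique" supporting reads (distinct alignment starts) with base quality >= `min_base_qual` |
| `min_base_qual` | Q23 | a supporting base below this counts toward coverage but not evidence |
| `end_exclusion_bp` | 10 | a variant supported only within the first/last 10 bp of reads is discarded (terminal cycles are mismatch-prone) |
| `splice_buffer_bp` | 5 | intronic calls within 5 bp (inclusive) of an exon-intron junction are discarded as mis-spliced alignment |
| `homopolymer_run` | 5 | minimal run length defining the homopolymer exclusion track |
| `dna_min_cov` | 20 | DNA coverage must be *strictly* greater, with zero reads of the edited base (any quality) |

Interpretation choices the literature leaves open, fixed here:

* **"Uniquely mapped"** is taken from the `NH` tag when present
  (`NH == 1`), falling back to `MAPQ >= 20`. Aligners differ in how they
  encode multi-mapping; `NH` is the most portable signal.
* **"Unique supporting reads"** means distinct alignment start
  coordinates, which also guards against PCR duplicates. A plain
  read-count rule is available via `unique_rule = "count"`.
* **Coverage vs evidence.** Depth statements (`min_cov`, frequency
  denominators, DNA coverage) count every filtered-read base regardless of
  base quality; the Q23 bar gates *evidence* only. Reported editing
  frequency is all supporting reads over total coverage, which keeps the
  estimate unbiased.
* **Splice-boundary distance** is 1-based from the junction: the first
  intronic base is at distance 1, and distance 5 is removed (inclusive).
  The rule applies only to intronic positions; an exonic call adjacent to
  a junction is legitimate.
* **Multiple DNA samples are pooled** by summing base counts before
  subtraction. The genome is one subject-level reference; pooling
  maximizes the coverage available to the strict `> 20X` rule (the
  default synthetic study uses two 30X genomes, pooled ~60X, mirroring a
  two-genome sequencing design).
* **Strand assignment** requires every overlapping annotated gene to
  agree; sites in genes on both strands are discarded as
  strand-ambiguous, intergenic sites as unassignable. Same-strand
  multi-gene overlap is allowed.
* **Cross-transcript genic context** resolves by the priority
  cds > utr5 > utr3 > noncoding_exon > intron, with consequence computed
  against the longest-CDS transcript that yields `cds`. Only one context
  per site is reported, and coding status is the most consequence-relevant
  label.
* A gene-model CDS whose length is not a codon multiple is accepted with
  a warning (annotation pipelines contain such models); only
  `predict_consequence()` refuses it, since only translation needs the
  frame.

## Downstream statistics

* **RPKM** is computed over the union of a gene's CDS exons: reads
  overlapping the CDS of several genes count toward each (simple overlap
  counting; no EM deconvolution). Genes without CDS have no defined
  feature length and report `NA` unless `feature = "exons"` is requested.
* **Junction usage**: a read supports a junction only if one of its
  CIGAR N gaps matches the intron exactly. The normalised value is
  log2(FPKM + 1) with each junction treated as a fixed-length feature of
  one read length — a zero-length feature has no FPKM, and this
  convention keeps cross-sample comparability while guaranteeing the
  value is 0 exactly when the count is 0. The mutually exclusive first
  junctions of the ADAR gene (J1 -> p110, J2 -> p150) are the motivating
  case; `junction_catalog()` labels junctions per gene in transcription
  order.
* **Editing matrices** mask cells below 10X coverage — those
  measurements would not have survived calling and are excluded from all
  statistics, not imputed. Heatmap sites require >= 10X and frequency
  > 0.4 somewhere; variably-edited sites require >= 10X in >= 2 samples
  and a call somewhere.
* **Sharing** treats a site as a binary edited/not variable per sample,
  ignoring frequency, over the union of called sites; strata (all /
  coding / non-synonymous) are row subsets.
* **Enzyme correlation** uses Pearson's r (one-sided, positive
  association) between per-site frequency and enzyme expression across
  samples with >= 10X at the site, requiring >= 3 usable pairs;
  Benjamini-Hochberg correction runs across all site-by-enzyme tests.
  Pearson matches the linear dose-response hypothesis being tested;
  Spearman is a flag away for monotone-but-nonlinear relationships.
* **Category enrichment** forms a 2x2 table per category over the
  expressed universe (RPKM >= 10 by convention), Fisher-exact one-sided,
  odds ratio Haldane-corrected (add 0.5 to every cell) when a cell is
  zero, and screens reported categories to OR > 10 with >= 2 edited
  genes — a deliberate bias toward effects too large to be annotation
  noise.

## What the synthetic generator emulates — and what it does not

`sim_config()` describes a complete toy study; `simulate_study()` writes
it to disk (FASTA, GFF3, four exclusion-track BEDs, one SAM per sample,
ground-truth TSVs). Defaults: a 1 Mb two-chromosome genome, 40
multi-exon genes (10% non-coding), six tissues at 15-40X transcript
coverage with 75 bp single-end reads, two 30X DNA genomes, 200 planted
edits at design frequencies 0.1-1.0 (30% intronic, each active in ~80%
of tissues), 100 germline SNPs (80% het), base errors at 0.001 with
degraded qualities (U{10..35} vs constant Q30), 2% multi-mapping (NH=2)
and 2% low-quality reads so the read filters have work to do, and
elevated intron retention in "brain" (0.30 vs 0.05) so intronic editing
is preferentially detectable there, reproducing the intronic-enrichment
phenomenon qualitatively.

Choices made once, for realism at desk scale: single-end reads suffice to
exercise every filter; error rate 0.001 is the Q30 scale of modern
Illumina data; 30X per DNA genome makes the pooled >20X rule hold with
margin while leaving the depth rule non-trivial per genome.

The generator does **not** model per-cycle error profiles, GC bias, PCR
duplicates, indels, hyper-editing clusters, or mapping bias around
variants. A green planted-truth test therefore establishes that the
cascade's logic is faithful and its operating characteristics are as
designed under idealized noise — not that real-data sensitivity will
match. Note also the designed stringency cost visible in the tests:
with zero-DNA-support required, a single DNA sequencing error matching
the edited base (probability roughly `60 * 0.001 / 3` per site at pooled
60X) vetoes a true edit, which is most of the small sensitivity gap below
100%.

## Numerical and degenerate-input conventions

* Internal coordinates are 0-based half-open everywhere; SAM/GFF3 are
  converted at the boundary and every output table is 1-based.
* Insertions contribute no pileup evidence; deleted positions contribute
  no base; splice gaps contribute nothing; soft clips are removed before
  read-end distances are measured.
* Sites with reference `N` are skipped. Constant frequency or expression
  vectors make a correlation undefined: the pair is reported untested
  rather than dropped silently.
* Ties in context priority are broken by CDS length (longest wins),
  making annotation deterministic across list orderings.
* All randomness flows from the single config seed; stages themselves are
  deterministic, and rerunning any stage with identical inputs produces
  byte-identical files (no timestamps are ever written).

## Worked example

```{r example, eval = FALSE}
dir <- tempfile("run")
run_simulate(dir, seed = 1)         # writes the toy study
rdds <- run_call(dir)               # full cascade + subtraction
run_annotate(dir)                   # context + consequence
run_quantify(dir)                   # RPKM, junctions, sharing, matrices
run_correlate(dir)                  # enzyme correlation over variable sites
run_report(dir)                     # summary.txt
rdds
```

On the default study this recovers the large majority of planted edits
detectable at their design frequency and depth, calls zero RDDs at SNP
sites, and reports only a handful of error-driven non-canonical sites —
the same shape of outcome the RDD strategy produces on real data, where
all-class RDD sets are dominated by the canonical A-to-I class after
filtering. The acceptance suite (`tests/testthat/test-acceptance.R`)
asserts these properties at fixed seeds and tolerances.

## Known limitations

* No hyper-editing detection: clustered edits that prevent alignment are
  invisible to a pileup-based caller.
* No de novo editing outside annotated genes — strand inference requires
  a gene model by design.
* The junction FPKM convention is one of several defensible
  normalizations; raw counts are always reported alongside.
* `NH`/MAPQ uniqueness is a heuristic when alignments come from tools
  with other conventions; the fallback threshold is configurable.
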