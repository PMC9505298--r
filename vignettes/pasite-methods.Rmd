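---
title: "Methods: poly(A) site discovery and PAS usage analysis with pasite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: poly(A) site discovery and PAS usage analysis with pasite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pasite)
```

## The problem

Cleavage and polyadenylation define the 3' end of almost every eukaryotic
mRNA. The cleavage site (CS) is selected by cis elements around it: a
polyadenylation signal (PAS) hexamer — canonically AAUAAA — roughly 10–35 nt
upstream, and a U/GU-rich downstream sequence element (DSE) a few to ~30 nt
downstream. Reads that carry a terminal poly(A) (or, reverse-complemented,
a leading poly(T)) pin the CS to a single genomic base, so EST and
full-length transcriptome archives are a free source of genome-wide pA
sites — at the price of two artifacts this package explicitly models:
oligo(dT) priming on genomic A-runs (internal priming), and the
indistinguishability of tail adenosines from templated genomic A's at the
cleavage junction.

`pasite` implements the full discovery pipeline — tail detection and
trimming, cleavage-event calling from alignments, internal-priming
filtering, clustering, positional nucleotide/hexamer profiling, PAS
assignment, and alternative-polyadenylation (APA) annotation — together
with a synthetic-data generator with complete ground truth, so every stage
is testable end to end without external data.

## Pipeline conventions

All internal coordinates are 0-based; the cleavage base is the **last
transcribed base**, and it is position 0 of every profile. BED output is
0-based half-open, GFF3 1-based closed. Genomic computation uses the DNA
alphabet; every reported table converts T to U at the output layer only.

### Tail detection (`detect_tail`)

A read is poly(A) evidence if it ends in an A-run or starts with a T-run of
at least 10 nt (configurable via `min_tail`). The tail is the *maximal
exact* terminal homopolymer run: no mismatches are tolerated, and N
terminates a run — the strictest reading, chosen so the ≥10-nt rule is
exercised exactly at its boundary. If both ends qualify, the longer run
wins and ties go to the 3' A tail (the direct-tail reading). Reads called
on the T side are reverse-complemented, so all downstream logic sees
transcript-sense sequence.

### Cleavage calling and the templated-A ambiguity

For a sense read aligned to the + strand the cleavage base is the reference
position of the alignment's last aligned base; on the − strand it is the
alignment's leftmost reference base. Records whose 3' read end is soft- or
hard-clipped are rejected (`"clipped-end"`): the cleavage base is not
anchored.

Pure-A tails create an unavoidable ambiguity: a read ending `...C` + A^k
is byte-identical whether the transcript ended at the C or at a genomic A
immediately after it, because trimming absorbs templated A's into the
apparent tail. The package's convention (`restore_templated_a`, applied by
default in `run_pa_pipeline`) restores **exactly one** templated A: the
called position is extended by one base iff a single genomic sense A
follows the alignment end. One A is the canonical case — cleavage
preferentially occurs 3' of the A of a CA dinucleotide — while longer
genomic A-tracts are never restored, so the A-rich downstream signature
that identifies internal priming is left intact. The function is exported
separately and the step can be disabled; `call_cleavage_events` itself
stops at the alignment end.

### Internal-priming filter (`internal_priming_filter`)

Two published operationalisations are implemented over the sense-strand
genomic window +1..+10 downstream of the called base: the *window rule*
(≥ 9 A in the 10 bases) and the *run rule* (≥ 8 consecutive A). The default
mode `"either"` applies both, since both criteria are in circulation and
they are not equivalent (`"CAAAAAAAAG"` trips only the run rule); each is
independently configurable (`window_len`, `min_at`, `min_run`, `mode`).
Windows truncated by a contig edge are evaluated as-is.

### Clustering (`cluster_events`)

Per chromosome, strand and evidence source, distinct event positions whose
adjacent gaps are ≤ 20 nt are chained by single linkage into one cluster —
transitively, so a chain of 20-nt gaps merges (a gap of 21 splits). The
representative position is the best-supported member; ties go to the
5'-most member. Evidence sources (EST vs long read) are clustered
separately and their totals added, mirroring how the reference study
reports per-source site counts; `merge_sources = TRUE` pools them instead.

### Profiling and PAS assignment

Flanks are 201-nt sense windows (−100..+100) around cluster
representatives; out-of-contig positions are masked and excluded from every
denominator. Mono- and dinucleotide profiles report per-position
frequencies (dinucleotides indexed by their first base). The hexamer scan
counts exact, overlapping occurrences by 5'-base position over −50..−1
(occurrences must lie wholly inside the range). PAS assignment searches the
40 nt upstream window for the 14 canonical hexamers in priority order —
AAUAAA first, then variants in descending reference usage
(`pas_hexamers()`) — mirroring the canonical-first convention of the
human/mouse studies this field builds on; among several occurrences of the
assigned hexamer the one closest to the modal PAS region is reported
(largest offset ≤ −11, else nearest −11). Sites with none of the 14 are
"Other".

The signal/noise classifier scores a hexamer's positional distribution as
`max count in −40..−10 / (median count over the scan + 1)` and calls
"signal" at a ratio ≥ 5 (exposed as `peak_ratio`). This is an invented
operationalisation of a qualitative peak-vs-scatter criterion. Its known
limitation: when elevated counts occupy about half of the 45 scanned
positions (e.g. a broad, flat offset distribution combined with wide
per-read jitter), the median itself rises into the signal and the ratio is
conservative. Under the generator's defaults AAUAAA scores well above the
threshold and UUUUUU is flat noise.

### Background model and tests

Positional composition is tested against an i.i.d. GC-content background:
with GC = 0.364, expected G or C frequency is 18.2% and A or U 31.8%. Each
(position, nucleotide) test is a 1-df goodness of fit on the two-cell split
(is-nucleotide vs not) via `stats::chisq.test`, without continuity
correction. Following the reference presentation, headline p-values are
uncorrected; `chisq_profile` adds a Bonferroni column for transparency. A
position with no unmasked flanks returns an NA marker rather than an error.

### APA annotation

The representative position is matched against same-strand genes only
(cleavage is strand-specific). Category precedence across annotations is
3'UTR > 5'UTR > exon > intron, where "exon" means CDS-bearing exon
sequence — the UTRs are reported separately so the four categories
partition genic space. A position inside a gene span but outside every
annotated feature is intronic; outside every same-strand gene, intergenic.
Among overlapping candidate genes the gene whose 3'UTR contains the site
wins, else the closest 3' end, ties broken by gene identifier. Genes with
≥ 2 distinct clusters are flagged APA-regulated and classified: all sites
in the 3'UTR → tandem 3'UTR; a 5'UTR / CDS / intronic site with the distal
site in the 3'UTR → the corresponding APA type (the 5'-most deviation
names the type); anything else → mixed.

## The synthetic-data generator

`simulate_pa_dataset` produces a genome (FASTA), gene models (GFF3), reads
(FASTQ), alignments of the trimmed sense reads (SAM) and per-site/per-read
truth tables. Everything derives from one seed and is byte-reproducible.

What it emulates, and the defaults (all `sim_config` arguments):

* **Genome**: i.i.d. bases at GC = 0.364, the reference genome's
  composition, so background expectations are exact by construction.
* **PAS usage**: hexamers drawn from the reference usage table
  (`pas_usage_reference()`, AAUAAA 51.6%, ..., none 10.1%) and written at a
  uniform offset in −30..−11 — the window where the reference data peaks.
  The 40-nt upstream window of *every* site is scrubbed of accidental PAS
  hexamers first: in a 63.6% AT genome ~3% of windows would otherwise
  contain a spurious canonical hexamer that the priority rule would
  promote, biasing recovered AAUAAA share upward by more than a point and
  making class identity untestable.
* **Cleavage base**: A with probability 0.62 (the observed position-0 A
  frequency), always as the CA dinucleotide with A-free +1/+2 — the minimal
  context that keeps the cleavage coordinate identifiable under pure-A
  tails given the single-A restoration convention above.
* **DSE**: bases +3..+27 rewritten with P(U) = 0.45 (U-rich against a
  31.8% background, the scale seen in real DSEs). The +1..+10 window of a
  true site is guaranteed to pass the priming filter, so filter sensitivity
  is measured on decoys alone.
* **Cleavage heterogeneity**: a site is heterogeneous with probability
  0.65; heterogeneous sites jitter each read by a rounded Gaussian (sd 1 nt,
  truncated at ±10). The site-level mixture, rather than homogeneous
  jitter, reflects that about a third of observed clusters show a single
  cleavage position even at depths where any per-read wobble would be
  visible. Exact cluster member-count fractions depend on read depth, so
  recovery tests compare against the truth table's realized heterogeneity,
  not against any printed value.
* **Sites per gene**: classes 1/2/3/4/5/>5 with probabilities
  0.2959/0.2941/0.17/0.11/0.07/0.06 (the class-1 mass is the complement of
  the reported 70.41% of genes with ≥ 2 sites; ">5" draws 6–8). The distal
  site of every gene is in the 3'UTR; earlier sites fall in
  3'UTR/intron/CDS/5'UTR with mix 0.6548/0.2486/0.0823/0.0143, solved so
  the expected overall category split matches the reported
  79.07/15.07/4.99/0.87 given the class distribution's mean. Sites of one
  gene are ≥ 60 nt apart so read jitter cannot merge neighbours.
* **Reads**: 5 per site; genomic (unspliced) sense suffixes of 150–400 nt
  ending at the (jittered) cleavage base, plus a pure-A tail of
  10 + Poisson(15) nt; half are emitted reverse-complemented. Tails are
  written error-free so the ≥10-nt rule is exercised by the configured
  length distribution, not by noise. Substitutions at `error_rate`
  (default 0) apply outside the tail.
* **Decoys**: a binomial fraction (default 5%) of reads are internal
  priming events at genomic A-runs ≥ 8 nt (sense A on either strand), with
  the run absorbed into the apparent tail — exactly the artifact the filter
  targets. Decoys are labelled in the read truth so removal rates are
  measurable; runs within 60 nt of a true site are excluded so decoys never
  contaminate true clusters.

What it does **not** emulate: splicing (reads are genomic suffixes — no
spliced alignment anywhere in the package), sequencing-quality models,
indels or chimeras, and expression-level variation beyond the constant
reads-per-site. Passing recovery tests therefore demonstrate correctness of
the analysis logic under the stated generative assumptions, not performance
on real noisy libraries.

### Truth bookkeeping

The read truth records both the *physical* templated end and the
*observable* cleavage coordinate (after tail absorption of templated A's
and single-A restoration). The two differ only where the templated end sits
in a genomic A-run; with the generator's CA/clean-downstream context they
coincide at unjittered true sites, which is what makes the noiseless round
trip exact. The SAM emitted by the generator is truncated to the post-trim
end, i.e. it carries no information a real aligner would not recover.

## Numerical and degenerate-input choices

Probability vectors must sum to 1 within 1e-9 (the bundled usage table is
normalised from percentages summing to 100.01). Profile row sums hold to
1e-9 at every unmasked position. Empty event sets cluster to an empty list;
an empty annotation loads as an empty model set; an empty scan range yields
an all-zero table. Representative ties break 5'-most; overlapping-gene ties
break by gene identifier; assignment-occurrence ties follow the
largest-offset-≤-−11 rule. Chromosome summaries flag a 0-gene chromosome
with an NA ratio instead of dividing by zero.

## Problem sizes used by the test-suite and acceptance script

Oracle-equivalence checks run 1,000 random clustering instances (≤ 200
positions each) against graph connected components, a naive substring
search over 100 random flanks, and direct window counting over a 100-kb
genome. Parameter recovery uses one dataset of ~7,700 genes / ~20,000
planted sites / ~100,000 reads on a 27-Mb genome, with every recovered
class frequency required to sit within 3 binomial standard errors of its
generating value; the round trip uses a noiseless ~400-site dataset. These
sizes give each class (down to ~1%) enough counts for a meaningful 3-SE
band while the whole suite stays in the minutes range on one CPU.

## Known limitations

* The hexamer signal classifier is conservative for broad flat positional
  distributions (see above); the threshold is a tunable, not a claim.
* The single-A restoration is a convention, not an inference: at sites
  cleaved after ≥ 2 genomic A's the reported coordinate is the 5'-most
  consistent base, and no convention can do better from pure-A-tailed
  reads alone.
* The naive exact-match aligner is for fixture-scale synthetic data only;
  real libraries should be aligned externally and ingested as SAM/BAM.
* Per-source clustering plus additive totals deliberately counts a site
  supported by both sources once per source, mirroring the reference
  reporting; use `merge_sources = TRUE` for a deduplicated catalogue.
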