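# pasite

Discovery and characterisation of polyadenylation (pA) sites from
poly(A)-tailed 3' end sequence evidence — ESTs and full-length
transcriptome reads — for anyone mapping cleavage-and-polyadenylation
landscapes in a genome with ordinary annotation: tail detection and
trimming, per-read cleavage calling from alignments, internal-priming
artifact removal, site clustering, positional nucleotide and hexamer
profiling, polyadenylation-signal (PAS) assignment, and
alternative-polyadenylation (APA) annotation. A fully parameterised
synthetic-data generator with ground-truth tables makes every stage
testable end to end.

## The method in brief

A read carrying a terminal poly(A) (or leading poly(T)) of ≥ 10 nt pins the
cleavage site (CS) to one genomic base: trim the maximal terminal
homopolymer, align the sense read, and take the last aligned base
(position 0; one templated A is restored at the junction, since cleavage
canonically occurs 3' of the A of a CA dinucleotide). Apparent sites whose
downstream genomic window +1..+10 is A-rich (≥ 9 A, or a run of ≥ 8
consecutive A) are internal-priming artifacts of oligo(dT) on genomic
A-tracts and are discarded. Surviving per-read events within ≤ 20 bp are
merged by single linkage into pA clusters.

Around each cluster the package profiles mono-/dinucleotide frequencies in
−100..+100, scans all hexamers by position, and assigns each site the
highest-priority PAS hexamer (AAUAAA, then its canonical variants) found
wholly within the 40 nt upstream window; sites with none of the 14 are
"Other". Positional composition is tested by a 1-df χ² against the genomic
GC background (GC = 36.4% ⇒ expected G/C 18.2%, A/U 31.8% per base).
Clusters are then placed on gene models (3'UTR > 5'UTR > CDS exon >
intron > intergenic), genes with ≥ 2 sites are flagged APA-regulated and
typed (tandem 3'UTR, intronic, CDS, 5'UTR, mixed).

## Worked example

Simulate a dataset with known truth (300 genes, ~800 planted sites,
defaults mirror the reference study conditions), run the pipeline, and
check recovery:

```r
library(pasite)
cfg <- sim_config(seed = 7, n_genes = 300, n_chromosomes = 2,
                  chrom_length = 600000)
sim <- simulate_pa_dataset(cfg)
run <- run_pa_pipeline(sim)

run$report$table1
#>      source raw_reads tailed_reads mapped_reads pa_clusters
#> 1 long_read      4198         4198         4198         796

head(run$usage, 4)
#>   hexamer   n   percent
#> 1  AAUAAA 387 48.618090
#> 2  AUUAAA  98 12.311558
#> 3  UAUAAA  36  4.522613
#> 4  AGUAAA  37  4.648241

round(run$report$member_fractions, 3)
#>     one     two several
#>   0.406   0.265   0.329

classify_hexamer_signal(run$scan, "AAUAAA")
#> $class
#> [1] "signal"
#> $peak_position
#> [1] -28
#> $peak_score
#> [1] 9.666667

validate_against_truth(run, sim)[c("recall_tol", "decoy_removal")]
#> $recall_tol
#> [1] 1
#> $decoy_removal
#> [1] 1
```

Reading the output: all 4,198 simulated reads carry a ≥ 10-nt tail and map;
after artifact filtering they collapse to 796 pA clusters — one per planted
site. 48.6% of sites use AAUAAA (the generator plants the reference usage
distribution, 51.6%, and this run of ~800 sites sits within sampling
error), with AUUAAA the second most used. 40.6% of clusters show a single
cleavage position. The AAUAAA positional distribution is a sharp peak at
−28, inside the canonical −30..−11 window, and the A frequency at
position 0 (58.0% in this run) is the global maximum of the A profile —
the planted CA cleavage context. Every planted site is recovered within
20 nt and every internal-priming decoy is removed.

Real data enter at the same functions with files instead of a simulation:
`run_pa_pipeline(list(genome = "genome.fa", annotation = "genes.gff3",
reads = <reads>, alignments = "aln.bam"))`. A thin CLI over these functions
ships in `inst/cli/pasite.R` (subcommands `simulate`, `prep`, `callsites`,
`profile`, `annotate`, `run-all`, `validate`).

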