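Package: pasite
Title: Poly(A) Site Discovery and Polyadenylation Signal Usage Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery and characterisation of polyadenylation (pA) sites from
    poly(A)-tailed 3' end sequence evidence (ESTs and full-length transcriptome
    reads). Detects and trims terminal poly(A)/poly(T) tails, calls per-read
    cleavage coordinates from alignments, removes internal-priming artifacts
    using genomic A-rich downstream windows, merges cleavage events into pA
    clusters, profiles mono- and dinucleotide composition around cleavage
    sites, scans for polyadenylation-signal (PAS) hexamers such as AAUAAA,
    tabulates PAS usage, classifies alternative polyadenylation (APA) by gene
    feature, and tests positional nucleotide frequencies against the genomic
    background. Includes a fully parameterised synthetic-data generator with
    truth tables so that every stage is testable end to end with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
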