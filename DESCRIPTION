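Package: minisplice
Title: Minigene Splicing Assay Analysis with Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of minigene splicing assays read out by long-read
    amplicon sequencing. Models exon-trapping minigene constructs with
    HGVS-style coding coordinates and intronic offsets, simulates
    nanopore-like cDNA amplicon reads from declared isoform mixtures,
    demultiplexes and splice-aligns reads against the construct, derives
    consensus exon coordinates from breakpoint frequencies, quantifies
    isoform abundances, classifies and aggregates splicing events
    (exon skipping, pseudoexon inclusion, intron retention, exon
    elongation), predicts protein consequences with a nonsense-mediated
    decay heuristic, and emits ACMG PS3/BS3 functional evidence with a
    five-class variant interpretation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
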