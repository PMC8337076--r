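Package: asmqc
Title: Quality Control and Comparative Statistics for Long-Read Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation statistics for de novo genome assemblies built from
    long (Nanopore-class) reads, oriented toward multi-species resources of
    insect-sized genomes. Computes contiguity statistics (Nx/NGx curves,
    N50/NG50, auN), BUSCO completeness summaries and the haplotig-purging
    decision rule, genome-size estimates from read depth over single-copy
    orthologous markers, per-site heterozygosity and Phred-scaled consensus
    quality (QV) from filtered variant calls with banded gVCF callable
    intervals, reference-based windowed QV decomposed by genomic element and
    error type, coding-indel impact accounting, weighted marker-adjacency
    (synteny) graphs with a ForceAtlas2-style layout, repeat-content
    summaries, and read-set statistics with seeded downsampling. A synthetic
    data module generates all required inputs with known ground truth so
    every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
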