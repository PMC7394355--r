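Package: itsprofiler
Title: Bacterial 16S-ITS-23S Amplicon Taxonomic Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for species-level taxonomic profiling of
    bacterial communities from amplicons of the 16S-23S internal transcribed
    spacer (ITS). Builds a reference database of 16S-ITS-23S regions from
    annotated genomes with ANI-based correction of species labels, predicts
    amplicons of degenerate universal primers by in silico PCR, performs
    primer-anchored quality control and exact dereplication of forward reads
    into amplicon sequence variants, classifies variants by consensus of
    top alignment hits, and benchmarks the whole chain on generated artificial
    communities, including read-length truncation experiments and alpha/beta
    diversity summaries. A synthetic-fixture generator with fully known ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
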