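Package: bhlhsurvey
Title: Identification, Classification and Expression Profiling of bHLH
    Transcription Factor Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of the basic
    helix-loop-helix (bHLH) transcription factor family in plants.
    Builds a position-specific scoring profile from a seed alignment of
    bHLH domains, locates the domain in candidate proteins by glocal
    dynamic-programming alignment, partitions it into basic, helix and
    loop regions, classifies each protein into four DNA-binding
    categories from its basic-region residues, profiles per-column
    conservation, reconstructs neighbor-joining phylogenies with
    bootstrap support and assigns subfamilies from labeled reference
    domains, calls cross-species orthologs under aligned-length and
    percent-identity filters, clusters redundant sequences, and analyses
    tissue expression (reference-gene normalization, subgroup
    clustering, tissue-specific block detection, and qPCR agreement).
    Includes a synthetic-data generator so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
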