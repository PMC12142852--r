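Package: magbroker
Title: Automated Submission Brokering for Metagenomics Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prepares and executes dependency-ordered archive submissions for
    genome-resolved metagenomics studies: scenario-driven configuration
    templates, metadata and file validation, fold-coverage inference from
    alignment maps, MIMAG quality tiers, environmental organism-level
    taxonomy resolution for bins and metagenome-assembled genomes (MAGs),
    sample-set XML and Webin-style manifest generation, receipt parsing, and
    accession tracking. Ships a deterministic mock registry, uploader and
    taxonomy service plus a toy-dataset generator so the whole workflow runs
    and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    dplyr,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
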