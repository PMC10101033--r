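Package: amplimatch
Title: Intragenomic 16S rRNA Redundancy and Degenerate Primer Pair Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies intragenomic 16S rRNA gene redundancy in prokaryotic
    genomes and evaluates IUPAC-degenerate primer pairs by in silico PCR.
    Detects matching amplicons (byte-identical amplicons shared across
    species), and computes primer coverage metrics: species coverage with no
    matching amplicons (SC-NMA), the overestimation factor (OF) and its
    copy-normalized form (OF-MA). Includes a k-mer-density 16S gene finder
    with conserved-motif anchoring, a synthetic-community generator with
    machine-readable truth tables, and taxonomic rank aggregation of copy
    number statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
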