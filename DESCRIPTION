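Package: pairsv
Title: Structural Variant Discovery from Paired-Read and Read-Depth Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and interprets structural variants (deletions, copy-number
    gains, inversions, and intra- and inter-chromosomal translocations) from
    coordinate-sorted paired-end alignments. Anomalous read pairs are classified
    against an empirical insert-size model, clustered into breakpoint-interval
    predictions, and combined with a GC-normalized, variance-stabilized
    read-depth segmentation to resolve simple and complex (copy-paste and
    cut-paste) rearrangements. A matched-normal subtraction mode reports somatic
    calls only, and a cascade filter routes unsupported calls through segmental
    duplication, simple-repeat and transposable-element annotation. Includes a
    synthetic-data module that simulates references, rearranged donor genomes
    and paired-read alignments with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
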