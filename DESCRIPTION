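Package: cisreg
Title: Scanning and Annotation of Cis-Regulatory Elements in Promoter and
    Transcript Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An annotated-scan toolkit for mapping regulatory elements in
    genomic sequence: degenerate IUPAC consensus motif scanning with mismatch
    budgets and exclusion patterns, CpG-island statistics and sliding-window
    island detection, spaced-dimer p53 response-element search, alternative
    promoter interval union and local-to-genomic coordinate mapping, and
    miRNA recognition-element prediction via an intermolecular
    minimum-free-energy dynamic program with extreme-value and Poisson
    significance statistics. Includes a seeded synthetic-sequence generator
    with planted regulatory structure and ground-truth records, so every
    pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
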