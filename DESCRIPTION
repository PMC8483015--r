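Package: fosmidr
Title: Fosmid Insert Assembly, Vector Removal and Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Toolkit for activity-based (functional) metagenomics fosmid
    clones. Simulates fosmid constructs and sequencing reads with known
    truth, counts, filters and subsamples reads to a target coverage,
    assembles them with a built-in de Bruijn graph assembler or an
    external assembler adapter, detects and removes the cloning vector
    with circularity-aware contig re-organization, calls coding
    sequences, and scores assemblies and annotations with
    alignment-based precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
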