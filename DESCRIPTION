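Package: genestitch
Title: Stitching Gene Fragments Across a De Bruijn Contig Graph
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns a de Bruijn assembly graph of contigs against reference
    gene sequences with an affine-gap network-matching dynamic program to
    infer gene paths (chains of contigs spelling more-complete genes),
    then filters, merges and extends those paths into gene graphs with
    representative sequences. Includes similarity-based subgraph seeding,
    intact-gene masking, a synthetic community simulator with a unitig
    graph builder for testing, and evaluation metrics (gene coverage,
    complete-gene counts, misassembly detection) for assembled genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
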