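Package: nucleoidgcc
Title: Genome Conformation Capture Analysis of the Bacterial Nucleoid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of genome conformation capture (GCC) data from circular
    bacterial chromosomes. Builds restriction-fragment interaction networks
    from mapped read pairs with an empirical ligation-control significance
    cutoff, estimates windowed GC-normalized relative copy number and corrects
    binned interaction frequencies for it, computes contact matrices,
    crossing-fragment profiles, loop-length and partner statistics, tests
    genomic region sets for spatial clustering against random-spacing (RS) and
    conserved-linear-spacing (CLS) circular permutation nulls with empirical
    p-values, and integrates gene-expression changes with spatial structure.
    Includes synthetic-data generators with known ground truth for every
    pipeline stage.
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
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    BiocGenerics,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
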