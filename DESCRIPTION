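Package: mirrortree
Title: Mirrortree Coevolution Analysis of Protein Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Distance-based phylogenetic pipeline for detecting coevolution
    between two protein families. From organism-labeled protein alignments it
    computes gap-aware p-distances with optional Poisson correction, infers
    neighbor-joining trees with bootstrap support and majority-rule-extended
    consensus under a collapse threshold, extracts patristic distance
    matrices, and measures inter-family tree similarity as the Pearson
    correlation between matched distance matrices with a permutation
    (Mantel-style) significance test. Includes a lipobox motif scanner for
    lipoprotein candidates and a coevolving-family sequence simulator (Yule
    species trees, 20-state Poisson substitution) so every stage can be
    calibrated and tested without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
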