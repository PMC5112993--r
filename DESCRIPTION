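Package: funcascade
Title: Multi-Label Protein Function Prediction by a Sequential Evidence
    Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts multi-label protein function over the 24 top-level
    FunCat categories by cascading three guilt-by-association scorers:
    similarity-weighted annotation transfer from alignment hits,
    weighted voting over protein-protein interaction partners, and a
    pseudo amino acid composition (PseAAC) cosine nearest-neighbour
    vote.  Includes the 270-dimensional PseAAC encoder with five
    physicochemical property profiles, an order-k accuracy evaluation
    harness with leave-one-out and repeated ten-fold cross-validation,
    branch-contribution accounting, extraction of candidate novel
    annotations ("false-wrong" first-order predictions), readers for
    FASTA, annotation CSV, alignment tabular and interaction files, and
    a seeded synthetic benchmark generator.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
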