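Package: pitchercomp
Title: Cross-Species Comparative Transcriptomics of Pitcher-Plant Feeding Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare prey-capture (feeding) transcriptome responses and
    tissue-specific expression between two independently evolved carnivorous
    pitcher plant lineages. Implements TMM normalization and FPKM summaries,
    negative-binomial per-tissue differential expression with
    Benjamini-Hochberg correction, orthogroup-level majority-vote response
    classification, batch self-organizing-map clustering on a hexagonal grid,
    Jaccard set similarity with a constrained permutation null, and screening
    of candidate orthogroups for convergent protein evolution. A synthetic
    two-species data generator with known ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    MASS,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
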