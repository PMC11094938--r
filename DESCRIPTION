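Package: fragstack
Title: Cell-Free DNA Fragmentomics Features and Stacked Detection Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts plasma cell-free DNA fragmentomics features from
    aligned paired-end sequencing data or plain fragment tables: a DELFI-style
    binned short/total fragment coverage profile, 9-bp codon end motifs read
    as three 3-bp motifs from the fragment 5' ends, and a per-gene nucleosome
    footprint around transcription start sites. Trains per-feature base
    classifiers (linear support vector machines and random forests), a
    stacked logistic meta-learner, and a final model fusing the stacked
    cancer score with serum CA19-9, with ten-fold cross-validation, a
    Gini-impurity decision cutoff, and ROC-based evaluation including
    coverage-downsampling experiments. Ships a seeded synthetic-cohort
    simulator that plants class effects in all three feature families so the
    whole pipeline can be exercised end to end without access-controlled
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    methods,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    tidyr,
    knitr
Config/testthat/edition: 3
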