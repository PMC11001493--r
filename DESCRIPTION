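Package: thermopred
Title: Multi-Threshold Protein Thermostability Classification from
    Language-Model Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies ensembles of per-temperature-threshold binary
    classifiers of protein thermostability on mean protein-language-model
    embedding vectors. Provides cluster-disjoint dataset construction from
    organism growth-temperature annotations, imbalance-aware multilayer
    perceptron training with per-epoch validation and maximum-MCC model
    selection, a multi-threshold consistency layer (left-hand and right-hand
    temperature-range labels with clash detection), per-segment sliding-window
    prediction, a binary-classification metric panel, and a synthetic-data
    generator so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
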