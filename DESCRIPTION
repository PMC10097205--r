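Package: leaderless
Title: Leaderless Secretory Protein Prediction for Plant Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identify candidate leaderless secretory proteins (LSPs) in
    plant proteomes. Builds a tiered-evidence database from per-isoform
    secretory-feature annotations, secretome observations,
    protein-protein interactions and PFAM/GO assignments; assembles
    labelled training sets under alternative signal-peptide modification
    schemes with identity-based redundancy reduction; trains balanced
    random-forest classifiers with false-positive-rate-calibrated
    decision thresholds, upper-quartile feature selection and
    modification-bias estimation; and applies fitted models to new
    protein FASTA input, including a synthetic proteome generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
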