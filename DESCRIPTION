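Package: metasecretome
Title: Metaproteomic Secretome Succession Analysis with Normalized
    Spectral Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy pipeline for time-resolved metaproteomic secretome
    data: validation of protein identifications (protein probability and
    unique-peptide thresholds), consensus extracellular-localization
    calling over signal-peptide, non-classical and Tat-pathway
    predictors, spectral-count normalization by molecular weight (NSpC),
    resolution of proteins with multiple candidate genera by the
    highest-abundance rule, keyword-based functional and pathway
    classification, and Simpson diversity indices over genera (Dt) and
    functional groups (Df). Includes transcriptions of a published soil
    community secretome study's abundance tables and a synthetic
    community-proteome generator with known ground truth, so every stage
    is testable without external downloads.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
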