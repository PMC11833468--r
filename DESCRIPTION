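Package: fourms
Title: Extraction Scoring and Taxonomy Building for 4M Framework
    Expressions in Clinical Text Messages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning short clinical text messages into evaluated
    extractions of Age-Friendly Health Systems 4M framework content (What
    Matters, Medication, Mentation, Mobility) and into a four-level semantic
    taxonomy. Includes corpus loading, deduplication and transfer-event
    windowing; a structured-output extraction contract with hallucination
    screening and a deterministic lexicon extractor; dual-annotator
    reconciliation and an agreement metric battery (Cohen's kappa, recall,
    F1, ROC AUC, Spearman's rho, binned kappa, MAE) with a performance gate
    and preference-pair export; embedding deduplication, Ward agglomerative
    clustering, threshold cuts and duplicate-resistant cluster labeling;
    concept-network querying and corpus summaries; and a fully synthetic
    corpus generator with ground-truth bookkeeping for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
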