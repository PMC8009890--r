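Package: erpstates
Title: ERP Microstate Analysis and Outcome Prediction for Infant EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing attentive brain states in infant
    event-related potentials (ERPs). Extracts classic Nc component
    features (mean amplitude, peak latency) from frontal-region
    averages, discovers prototypical ERP microstate maps by
    atomize-and-agglomerate hierarchical clustering (AAHC) with
    cross-validated selection of the number of maps, fits maps to
    individual ERPs by spatial correlation, and extracts per-map
    duration and mean global field power features. Downstream
    prediction of a categorical outcome uses genetic-algorithm feature
    selection with a cross-validated support-vector-machine fitness,
    and prediction of a dimensional outcome uses elastic-net
    regression with nested cross-validation; uncertainty is
    quantified by bootstrap and permutation (shuffle) tests. A
    synthetic-cohort generator with planted microstate structure
    supports end-to-end validation without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
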