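Package: seizecca
Title: Canonically Correlated Sparse Autoencoders with Swarm-Based
    Feature Selection for EEG Seizure Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Classifies one-second EEG segments (UCI epileptic-seizure
    layout: 178 numeric features plus a class label) with a deep
    canonically correlated sparse autoencoder. Feature subsets are chosen
    by a coyote-optimization wrapper that trades classifier error against
    subset size, and classifier hyperparameters are tuned with a krill
    herd swarm. Includes min-max preprocessing with leakage-safe
    fold-wise fitting, a deterministic synthetic EEG-table generator with
    planted class-informative features, a stratified k-fold evaluation
    harness reporting sensitivity, specificity, precision, accuracy,
    F-score, MCC and one-vs-rest ROC/AUC, tidy() and glance() methods for
    fitted objects, ggplot2 plotting, and a command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
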