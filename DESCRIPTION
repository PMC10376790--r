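Package: fuzzytree
Title: Fuzzy Decision Tree Classification for Heterogeneous Biomedical Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified fuzzy classification pipeline for heterogeneous biomedical
    data: spectral feature extraction for fixed-rate signals, principal-component
    dimensionality reduction, fuzzy C-means fuzzification of crisp numeric and
    categorical attributes, and fuzzy classifiers (an information-theoretic fuzzy
    decision tree with alpha/beta pruning, and a fuzzy naive Bayes baseline).
    Includes confusion-based evaluation metrics, hold-out and random-subsampling
    protocols, seeded synthetic generators for four biomedical data archetypes
    (signal, wide laboratory, mixed clinical, expert fuzzy tables), decision-table
    and rule export, and JSON model serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
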