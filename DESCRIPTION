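Package: transdx
Title: Transdiagnostic Case-Control Classification Benchmarks for ICD-10
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates case-control classification benchmarks
    across ICD-10 diagnostic groups in large epidemiological cohorts.
    Provides hierarchical ICD-10 group retention with comorbidity
    accounting, prioritized unique case-control matching (sex, then age,
    then head motion), a scale/PCA/classifier evaluation engine (random
    forest, support vector, k-nearest neighbors) run over stratified
    shuffle-splits with nested hyperparameter tuning, leave-one-site-out
    cross-validation, a one-vs-rest multiclass formulation, a conservative
    chance-level significance criterion based on the standard deviation of
    split-wise accuracies, false discovery rate correction across feature
    sets, and an oldest-vs-youngest age-classification benchmark.  A
    synthetic cohort generator with planted covariate, comorbidity and
    feature effects makes every stage testable without access-restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
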