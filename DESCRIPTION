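Package: lppselect
Title: Variable Selection with Low-Prevalence Binary Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares random-forest and stepwise-regression variable selection
    when many candidate predictors are rare binary indicators, as arises in
    clinical screening tools built from electronic health records. Provides a
    seeded synthetic-cohort generator calibrated to a target outcome
    prevalence, repeated-forest permutation-importance ranking with sequential
    nested-model selection, forward and backward AIC stepwise logistic
    regression, ROC statistics (Mann-Whitney AUC, DeLong's test for two
    correlated ROC curves, stratified-bootstrap confidence intervals), and a
    prevalence-threshold simulation harness that tracks importance-rank
    distributions, retention frequencies, and cross-validated AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
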