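Package: prsbench
Title: Simulation and Benchmarking of Genetic Disease Prediction with
    Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Monte Carlo toolkit for studying how well genotype-based
    classifiers and polygenic risk scores (PRS) predict a binary disease
    phenotype under controlled genetic architectures. Simulates balanced
    case/control cohorts of multilocus genotypes from per-site penetrance
    models (additive, dominant, recessive, null) with Beta-distributed risk
    allele frequencies under Hardy-Weinberg equilibrium; estimates allelic
    odds-ratio PRS weights; benchmarks logistic regression, naive Bayes,
    random forest and feed-forward neural network classifiers by test-set
    ROC AUC, with optional LASSO feature selection; and evaluates closed-form
    AUC predictions from PRS summary statistics under liability-threshold and
    log-risk models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    e1071,
    nnet,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
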