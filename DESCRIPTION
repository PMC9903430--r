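Package: mlprs
Title: Machine-Learning SNP Panel Selection and Polygenic Risk Scoring for
    Case/Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A machine-learning pipeline for SNP-based binary disease
    prediction from diploid genotype dosages. Provides cohort input and
    output (VCF and tabular dosage formats), fixed-proportion train/test
    partitioning, SNP-level quality control (minor-allele frequency,
    missingness, exact Hardy-Weinberg test), iterative model-based genotype
    imputation, stability feature selection by recursive feature elimination
    with cross-validation over resampled subsets, minimal-panel determination
    by stepwise inclusion, a five-classifier evaluation suite with a
    random-panel null AUC distribution and exact Shapley attributions, and a
    missingness-normalized polygenic risk score with a per-individual risk
    calculator. A synthetic case/control genotype simulator with a known
    causal panel makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    ranger,
    e1071,
    xgboost,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
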