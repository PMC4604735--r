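Package: ctpl
Title: Prognostic Score Validation for Critically Ill Patients with Cirrhosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a panel of liver-specific and general ICU severity
    scores for patients with cirrhosis admitted to intensive care -- the
    Child-Turcotte-Pugh (CTP) score, its lactate-augmented variant CTP+L,
    and configuration-driven MELD, UKELD, SOFA, CLIF-SOFA, APACHE II and
    Royal Free Hospital (RFH) scores -- and runs the validation pipeline
    used to assess them against ICU mortality: univariate outcome
    association (Welch t, Mann-Whitney U, chi-squared with Yates
    correction, Fisher exact), empirical ROC analysis with DeLong
    confidence intervals and Youden cut points, paired DeLong comparison
    of correlated ROC curves, binary logistic regression with
    deterministic stepwise AIC selection, and cross-cohort cut-point
    transport with chi-squared goodness-of-fit and the phi coefficient.
    A synthetic-cohort generator calibrated to published cohort summary
    tables makes every pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
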