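Package: sbifinder
Title: Detection of Silent Brain Infarction and White Matter Disease in
    Neuroimaging Reports
Version: 1.0.0
Authors@R:
    person("Morgan", "Hale", email = "morgan.hale@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying incidentally discovered silent brain
    infarction (SBI) and white matter disease (WMD) in free-text
    neuroimaging (CT/MRI) reports. Provides a lexicon-driven rule-based
    information-extraction pipeline (sentence segmentation, section
    detection, regular-expression concept matching, negation/temporality/
    experiencer context assignment, and heuristic document-level
    labelling), a convolutional neural network sentence classifier over
    word embeddings with logistic-regression, linear-SVM and
    random-forest baselines, pointwise mutual information keyword
    ranking, evaluation statistics (confusion-matrix metrics, Cohen's
    kappa, exact McNemar test, F-measure), and a synthetic report
    generator that emulates two documentation styles so the whole system
    can be trained and validated without access to restricted clinical
    corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stringi,
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
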