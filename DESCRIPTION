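Package: cfae
Title: Quality-Gated Nonlinear Characterization of Fractionated Atrial Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the atrial substrate from bipolar
    complex fractionated atrial electrograms (CFAEs) recorded during atrial
    fibrillation. Provides a synthetic fractionated-electrogram generator
    with ground-truth annotations, powerline-interference removal and
    Botteron-style envelope preprocessing, automated segment-quality gating
    with product propagation across window lengths, nonlinear substrate
    indices (sample entropy, recurrence-plot determinism, atrial fibrillation
    cycle length, dominant frequency), intra-recording and intra-patient
    stability assessment via the coefficient of variation with a
    nonparametric testing battery, and correlation-filtered, Random-Forest
    ranked coarse-tree classification of paroxysmal versus persistent
    atrial fibrillation with leave-one-patient-out cross-validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    randomForest,
    rpart,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    lmtest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
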