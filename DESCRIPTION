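Package: aciglm
Title: Auditory Classification Images from Phoneme-in-Noise Categorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulation and analysis of phoneme-in-noise categorization
    experiments with the Auditory Classification Image (ACI) method.
    Generates formant-synthesized VCCV targets mixed with white noise under
    a 3-down-1-up adaptive staircase, transforms stimuli through a
    gammatone-style cochleogram front-end, simulates linear-template
    observers, estimates per-listener spectro-temporal decision templates by
    penalized (smoothness-prior) logistic regression with cross-validated
    penalty selection, and provides group-level statistics (pixelwise FDR
    t-maps, cluster-based permutation tests, weight-set extraction) together
    with auto/cross-prediction deviance and signal-detection analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
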