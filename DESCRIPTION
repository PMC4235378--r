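Package: vocalsniff
Title: Coupling of Rodent Ultrasonic Vocalizations to the Sniff Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how rodent ultrasonic vocalizations (USVs) are
    temporally bound to the respiratory cycle. Detects USVs in high-bandwidth
    audio by multitaper spectral entropy, assigns calls to subjects from paired
    microphones, reconstructs and segments intranasal-pressure sniff traces
    (Fourier deconvolution of tubing distortion, threshold-crossing landmarks,
    three-point phase warping), computes sniff-vocalization coupling statistics
    (vocal ratio, exhalation prolongation regressions, phase locking,
    silence-threshold call segmentation, rate-conditioned call metrics), and
    tests call-bout structure against constant- and variable-probability
    surrogate ensembles. Ships a synthetic-data generator producing paired
    two-channel ultrasonic audio and intranasal-pressure traces with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tools,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
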