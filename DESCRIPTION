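Package: mcgpipe
Title: Smartphone Mechanocardiography Feature Extraction and Cardiac
    Condition Classification
Version: 0.1.0
Authors@R:
    person("MCG", "Pipeline Maintainers", email = "mcgpipe@example.org",
           role = c("aut", "cre"))
Description: Signal processing and machine-learning pipeline for
    six-axis smartphone mechanocardiography (joint seismocardiography and
    gyrocardiography). Provides brick-wall band-pass and moving-average
    breathing removal, fixed 10-second episode segmentation, short-term
    autocorrelation heart-rate estimation, rhythm features (heart-rate
    variability, approximate and spectral entropy, turning-point ratios),
    morphology features (sub-band energies and one-dimensional uniform
    local binary pattern histograms), leave-one-subject-out evaluation of
    kernel support vector machine and random forest classifiers with
    per-recording majority voting, and a synthetic six-axis signal
    simulator for normal sinus rhythm, atrial fibrillation, coronary
    artery disease and ST-elevation myocardial infarction phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    quadprog,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
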