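Package: retistate
Title: Arousal-State Modulation Analysis for Retinal Output Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of behavioral-state (arousal) modulation of
    visual responses in two-photon calcium imaging of retinal boutons and
    extracellular recordings of optic-tract axons. Provides neuropil-corrected
    delta-F-over-F preprocessing with unit quality control, iterative
    kernel/trial-gain estimation of grating responses, wrapped-Gaussian
    direction tuning fitted jointly across pupil states with shared shape
    parameters, regularized spatio-temporal ON/OFF receptive-field mapping
    with a running-speed filter, circular-shift null tests for correlations
    between neural activity and running or pupil size, spike-amplitude
    drift quality control, and a ground-truthed synthetic-session generator
    for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
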