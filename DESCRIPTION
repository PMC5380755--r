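Package: nirsload
Title: Continuous Working-Memory-Load Decoding from Whole-Head fNIRS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for decoding continuous
    working-memory load from multichannel functional near-infrared
    spectroscopy (fNIRS) recorded during an n-back speed-regulation
    driving task. Provides a forward model generating two-wavelength
    raw intensities with workload-locked hemodynamics and physiological
    artifacts; modified Beer-Lambert conversion to oxy-/deoxy-hemoglobin
    concentration changes; coefficient-of-variation channel rejection and
    least-squares FIR low-pass filtering; PCA-truncation denoising with
    lasso regression inside nested trial-level cross-validation yielding
    a continuous predicted-workload trace; channel-wise univariate
    correlation maps with decoding-weighted group averages; and linear
    mixed-model trend tests for trial-wise behavioral and cardiac
    parameters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    glmnet,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
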