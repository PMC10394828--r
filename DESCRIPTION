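Package: tiltpress
Title: Tilt-Test Analysis of Craniospinal, Vascular, and Abdominal Pressure Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-channel physiological pressure
    recordings acquired during tilt-table testing. Provides a synthetic
    multi-compartment waveform generator with known ground truth, artifact
    rejection and zero-phase Butterworth preprocessing, per-step mean and
    pulse-pressure extraction with Pearson correlation to body angle,
    FFT-ratio transfer functions from carotid arterial pressure to
    craniospinal, venous, and abdominal channels with resonance and
    roll-off quantification, and a trigonometric hydrostatic predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
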