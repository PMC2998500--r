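Package: cardiogate
Title: Acoustic Cardiac Triggering Signal Chain and Trigger-Fidelity Analysis
Version: 0.1.0
Authors@R: person("CardioGate", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing cardiac gating of magnetic resonance
    acquisitions from physiological waveforms. Implements the acoustic
    cardiac triggering (ACT) signal chain -- calibrated sound pressure
    level spectrograms, an inverse Chebyshev heart-sound low-pass filter
    and first-heart-tone trigger detection -- together with a synthetic
    generator for multi-rate physiological recording sessions
    (electrocardiogram with magneto-hydrodynamic distortion, pulse
    oximetry, phonocardiogram, respiration and gradient acoustic noise),
    a trigger-fidelity pipeline (breath-hold gating, cross-correlation
    R-R segmentation, tickmark reassignment, jitter and interval
    statistics) and agreement statistics (Bland-Altman, exact Wilcoxon
    matched-pairs with midranks, paired t).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
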