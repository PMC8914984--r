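Package: emgfatigue
Title: Objective Muscle Fatigue Detection from Surface Electromyography
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects muscle fatigue from single-channel surface
    electromyography (sEMG) with a double-step binary classifier: an
    integrated-EMG gate that verifies sustained contraction, followed by a
    sub-band spectral comparison in which the signal is split into
    low-frequency (25-79 Hz) and high-frequency (80-350 Hz) sub-signals and
    the difference of their instantaneous mean FFT amplitudes serves as the
    fatigue index. Includes Butterworth preprocessing (band-pass and
    power-line band-stop), overlapping rectangular-window segmentation,
    time- and frequency-domain features (integrated EMG, mean and median
    frequency), confusion-matrix evaluation utilities, a synthetic sEMG
    generator with controllable fatigue structure, and a command-line front
    end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
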