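Package: ppgsim
Title: Synthesis of Regular and Arrhythmic Photoplethysmography Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic photoplethysmography (PPG) waveforms from a
    two-Gaussian polar pulse model. Supports regular rhythms with Gaussian
    RR-interval variability and three classes of premature atrial contraction
    groups (compensation, reset, interpolation), per-beat morphology sampling
    from template parameter distributions, cubic-spline smoothing of beat
    junctions, and SNR-calibrated white Gaussian plus multi-frequency
    sinusoidal noise. Includes a constrained nonlinear least-squares fitter
    that recovers the six pulse-model parameters from an observed single-beat
    trace, seeded end-to-end reproducibility, and CSV + JSON-sidecar
    serialization with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
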