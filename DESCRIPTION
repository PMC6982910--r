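Package: bruxsense
Title: Occlusal-Force Biofeedback Signal Analysis for Sensor-Embedded Dental Splints
Version: 0.1.0
Authors@R: person("bruxsense", "developers", role = c("aut", "cre"),
    email = "maintainers@bruxsense.invalid")
Description: Analysis stack for intraoral occlusal-force monitoring with
    piezoresistive sensor splints: a synthetic bite-episode signal simulator,
    an ADC coding model with a sleep/wake threshold-triggered occlusion event
    detector, translation-invariant (cycle-spinning) wavelet denoising with
    the Donoho universal threshold, per-window monitoring statistics and
    feature extraction, a one-dimensional inverted-bottleneck residual
    convolutional network that grades the occlusal-adjustment level, and an
    end-to-end session pipeline with a threshold feedback loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
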