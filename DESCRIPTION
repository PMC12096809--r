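Package: vocsel
Title: Selectivity of Simulated Cortical Responses to Bat Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how well single cortical units
    discriminate bat vocalizations. Synthesizes a 15-call stimulus library
    (echolocation, appeasement and aggression categories), simulates
    frontal-auditory-field-like and dorsal-auditory-cortex-like spiking
    units as envelope-driven inhomogeneous Poisson processes, derives
    pure-tone tuning metrics (frequency response areas, best and
    characteristic frequency, Q10dB, response latency and duration),
    computes response-strength preference indices for call categories and
    single calls, and classifies single-trial spike patterns into call
    categories by nearest-template Euclidean distance on Gaussian-smoothed
    peri-stimulus time histograms, yielding confusion matrices and a
    selectivity index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
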