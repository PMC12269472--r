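Package: megpacr
Title: Phase-Amplitude-Coupling Resting-State Networks from MEG Source Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cortical resting-state networks from source-space MEG
    recordings with the megPAC approach: per-vertex maximum phase-amplitude
    coupling over a low-frequency phase grid (2-30 Hz) and a high-gamma
    amplitude grid (80-150 Hz), synthesis of a slow megPAC surrogate series
    sampled at extrema of the coupled low-frequency component and resampled to
    10 Hz, surface smoothing, correlation + singular value decomposition
    network extraction, and group statistics (jackknife leave-one-out
    ensembles, phi-coefficient template matching and overlap tests,
    vertex-wise factorial ANOVA with false-discovery-rate control, and a
    low-frequency-component ANOVA). Includes a synthetic source-space data
    generator with planted networks and condition effects so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
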