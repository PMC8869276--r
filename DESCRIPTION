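Package: thermofatigue
Title: Thermal-Imaging Analysis of Exercise-Induced Fatigue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for analysing infrared-thermography
    recordings of fatiguing exercise. Tracks rectangular regions of
    interest (ROIs) across thermal video by normalized cross-correlation,
    extracts per-frame mean-temperature traces, computes time-domain
    (pre/post temperature change) and frequency-domain (band-limited
    power-spectral-density change over the five vasomotion bands)
    features, and runs the repeated-measures ANOVA / LSD post hoc /
    Pearson-correlation statistics layer against ratings of perceived
    exertion. Includes a synthetic thermal-video generator with known
    ground truth so every stage is testable without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
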