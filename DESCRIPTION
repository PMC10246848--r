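Package: crp
Title: Canonical Response Parameterization for Stimulation-Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven analysis of repeated single-pulse stimulation-evoked
    voltage responses (cortico-cortical evoked potentials and related
    event-triggered data). Determines whether a reproducible response exists
    via semi-normalized single-trial cross-projections, estimates the
    response duration from the peak of the time-resolved projection profile,
    extracts a canonical response shape with linear kernel PCA, and
    parameterizes each trial as a scaled projection of that shape plus a
    residual, with per-trial signal-to-noise ratio, explained variance,
    extraction and parameterization significance, automated artifact-trial
    rejection, and a synthetic-session generator for validation and null
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
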