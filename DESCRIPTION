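Package: trackmig
Title: Nucleus Tracking and Migration Statistics for Time-Lapse Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects fluorescently labeled nuclei in time-lapse microscopy
    stacks, links them into cellular tracks, and computes per-cell and
    population-level migration statistics: speed, angle of trajectory, signed
    angle of deflection, mean squared displacement, persistence time via the
    persistent-random-walk model, and a paired directional-variance index of
    collective migration with random-pairing and random-angle controls.
    Includes a synthetic-data generator (persistent random walks, neighbor
    alignment, rendered nucleus videos) so every stage of the pipeline can be
    validated against ground truth, plus batch processing over folders of
    videos and pre-computed track tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
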