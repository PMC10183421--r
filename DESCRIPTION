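Package: fibsafe
Title: Safe Drilling Corridors on the Distal Fibula for Syndesmotic
    Stabilization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-dimensional geometric analysis of distal fibula axial
    cross-sections for planning syndesmotic stabilization: shape
    classification and lateral-surface aspect ratio, finite-diameter
    drill-tunnel simulation for anteriorly angulated, posteriorly
    angulated and center-center device orientations, Procrustes landmark
    registration onto a reference section, and cohort-level safe-corridor
    statistics.  Includes a synthetic cross-section cohort generator that
    reproduces the statistical structure the analysis assumes, so every
    stage is testable without patient imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
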