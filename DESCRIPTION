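Package: kbanhatti
Title: K-Banhatti Topological Descriptors and Polynomial QSPR Models for
    Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the five K-Banhatti degree-based topological
    descriptors (B1, B2, HB1, HB2 and the harmonic Hb) of
    hydrogen-suppressed molecular graphs via edge partitions, with an
    independent incidence-sum cross-check, and fits linear through
    biquadratic ordinary least squares models relating the descriptors to
    physicochemical properties (enthalpy of vaporization, molecular
    weight, molar volume, flash point, molar refractivity) of a packaged
    panel of 20 anti-pneumonia drugs.  Includes loaders for edge-list and
    JSON graph fixtures, a molecule-like random graph generator for
    property-based testing, row-set sensitivity analysis for the
    regression grid, and a reproduction report of the published
    model-quality grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    ChemmineR,
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
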