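Package: warblerspace
Title: Acoustic Signal-Space Partitioning in Warbler Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing how singing migrant warblers dynamically
    overlap the acoustic signal space of a breeding warbler community.
    Builds a two-dimensional signal space from six song traits by PCA on
    the correlation matrix of per-male trait means, represents each
    species' signalling niche as the convex hull of its males' scores,
    computes exact pairwise and group-wise niche overlap by convex-polygon
    geometry, reconstructs the time-varying community from filtered
    checklist occurrence data, fits Poisson and binomial GLM time-course
    models of overlap, runs a randomization null model for niche
    dispersion (Z scores), and relates patristic distance to distance in
    signal space. Includes a synthetic-data generator emulating song-trait
    tables, checklists, and phylogenies so the whole pipeline is testable
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    ape,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
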