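Package: myxotrack
Title: Multiscale Single-Cell Tracking and Motility Analysis of Bacterial Predation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the multiscale motility behaviour of predatory
    Myxococcus xanthus communities invading an Escherichia coli prey lawn from
    time-lapse label-mask microscopy. Provides frame-to-frame linking of
    segmented cell masks into single-cell trajectories, Voronoi-tessellation
    local density and dilation-based long-range clustering, classification of
    cells into scout, loner and swarm classes, per-track kinematics (speed,
    gyration radius, mean-squared-displacement directionality exponent),
    class-transition statistics, trail maps with structural-similarity overlap
    analysis, prey-fluorescence decay quantification, and a synthetic
    predation-scene simulator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
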