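Package: cellmech
Title: Single-Cell Mechanophenotyping of B Lymphocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell mechanical phenotyping of
    primary B lymphocytes: Hertz-Sneddon fitting of atomic force microscopy
    (AFM) force-indentation curves into per-cell cortical stiffness,
    hypoosmotic swelling kinetics from bright-field time-lapse stacks
    (H-maxima segmentation, tracking, exponential radius fits),
    super-resolution actomyosin morphometry (meshwork density, skeleton-based
    filament length and branching, Manders colocalization), real-time
    deformability cytometry (RT-DC) contour shape descriptors with
    area-ratio gating, and Mann-Whitney cohort comparisons. Includes a
    seeded synthetic-data generator producing force curves, image stacks,
    two-channel images and event contours with ground-truth tables, so every
    stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    minpack.lm,
    igraph,
    EBImage,
    tiff,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    broom
Config/testthat/edition: 3
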