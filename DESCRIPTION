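Package: senescan
Title: Imaging-Flow-Cytometry Quantification of Senescent Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative, cell-type-specific identification of senescent
    cells from per-cell multi-channel image stacks of the kind produced by
    imaging flow cytometers. Provides per-cell mask derivation and scalar
    feature extraction (bright-field mean pixel for SA-beta-gal darkness,
    nuclear gamma-H2AX focus counting, fluorescence marker intensities,
    cell area and aspect ratio, focus-quality metrics), hierarchical
    control-referenced gating with boolean marker combinations, population
    statistics (percent positive, cell-area comparisons, two-sample tests),
    and a seeded synthetic cell-image generator with ground-truth labels so
    the entire pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
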