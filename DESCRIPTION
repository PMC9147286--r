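Package: bollcount
Title: Supervised and Weakly Supervised Counting of Cotton Bolls in Proximal Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for counting cotton bolls (and similar bright plant
    organs) in proximal RGB imagery. Provides deterministic tiling of
    full-plant images into fixed-size zero-padded tiles with plant-level
    count aggregation, reading and writing of VGG Image Annotator point and
    polygon exports with count binning and rotation-based class balancing, a
    fully supervised convolutional count-regression model, two weakly
    supervised counters (a multi-branch model trained only on
    presence/absence labels via classifier- and spatial-consistency losses,
    and a density-map model trained with image-level lower-count
    supervision), the accompanying evaluation protocol (per-bin RMSE over
    repeated training runs, median-of-runs error histograms, least-squares
    calibration), and a seeded synthetic scene generator so the whole
    pipeline is testable on CPU without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
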