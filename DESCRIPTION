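Package: miiquant
Title: Mycelial Biomass Quantification from Microscopic Image Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rapid quantification of filamentous-fungal biomass in submerged
    culture from bright-field micrographs. Implements an ImageJ-style image
    transformation chain (grayscale conversion, gray-level thresholding,
    rolling-ball background subtraction, contrast enhancement, dilation,
    median filtering, small-object noise removal) that isolates mycelium
    pixels and summarises each micrograph as a microscopic image intensity
    (MII) statistic; calibrates MII against dry cell weight (DCW, mg/L) by
    simple linear regression with full verification statistics, prediction
    with a symmetric accuracy metric, and per-dilution-factor goodness-of-fit
    analysis. Includes a seeded synthetic-micrograph generator (branching
    hyphae, spores, pellets, uneven illumination, impulse noise) with ground
    truth, so every pipeline stage and the calibration statistics are
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    jpeg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
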