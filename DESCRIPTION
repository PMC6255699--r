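Package: xylemct
Title: Leaf Xylem Embolism Analysis from MicroCT Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying drought-induced xylem embolism in leaf
    veins from microCT cross-section image pairs. Segments gas-filled conduit
    lumina, converts conduit areas to theoretical hydraulic conductances via
    the Hagen-Poiseuille relation, computes the theoretical percent loss of
    conductance (PLC) from pre-cut/post-cut scan pairs, fits sigmoidal
    vulnerability curves to extract P50 and slope with uncertainty, compares
    organs by confidence-interval overlap, and runs the accompanying
    anatomical trait statistics. A synthetic-data module generates conduit
    populations, microCT-like scan pairs, centrifuge PLC series and trait
    tables with known ground truth so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
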