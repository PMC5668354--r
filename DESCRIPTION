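Package: mitomech
Title: Mechanical Phenotyping of Confined Mitotic Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microcantilever-based mechanical phenotyping of
    single mitotic cells rounding against plate confinement. Converts cantilever
    force traces and midplane cell images into equilibrium rounding forces,
    intracellular (rounding) pressures and cell volumes under a cortical-shell,
    liquid-core model with circular side profiles; quantifies cortex-to-cytoplasm
    fluorescence localization ratios of myosin II and actin; and implements the
    statistics of an RNAi mechanophenotyping screen (daily control normalization,
    per-round tests, primary and secondary hit calling, phenotype classification).
    A synthetic-data generator with known ground truth stands in for the
    instrument, so every stage of the pipeline is verifiable by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
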