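Package: spheroidq
Title: Quantification of Tumor Spheroid Co-Culture Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying collective behavior in tumor spheroid
    co-cultures of drug-sensitive and drug-resistant cancer cells.
    Implements plate-assay normalization and three-parameter dose-response
    (IC50) fitting, logistic-growth doubling times, the chemoprotection
    coefficient (observed over expected mixed-culture viability), radial
    intensity profiling and the edge-to-center cell-sorting statistic for
    two-population spheroids, integrated propidium-iodide death scoring,
    nuclei-seeded cell segmentation with junction-enrichment ratios,
    collagen-invasion distance measurement, and Ct-based copy-number and
    expression arithmetic. A synthetic-data module generates images and
    assay tables with known ground truth so every stage can be validated
    end-to-end.
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
    generics,
    jsonlite,
    readr,
    tiff,
    EBImage,
    minpack.lm,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
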