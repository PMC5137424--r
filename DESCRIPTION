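Package: predep
Title: Differential Polycomb Occupancy at Polycomb Response Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Comparative ChIP-seq occupancy analysis at Polycomb Response
    Elements (PREs). Scores 1 kb candidate elements with a top-window read
    density statistic, depth-normalizes across libraries, contrasts genotypes
    with a symmetric relative difference, and classifies each element by how
    strongly PRC2 recruitment depends on PRC1. Includes threshold-and-cluster
    peak calling with summit detection, cumulative occupancy profiles around
    isolated peaks with loess smoothing and difference curves, randomized
    genomic background estimation, and a seeded synthetic coverage-track
    generator with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
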