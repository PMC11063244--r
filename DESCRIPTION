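Package: cocoar
Title: Cross-Species Co-Expression Analysis via Orthology Transposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates differential-expression datasets from multiple fungal
    species by transposing each up-regulated gene list into the gene space of a
    chosen receiver species through orthogroup membership, decomposing the
    transposed sets into exhaustive Venn regions, and reporting genes conserved
    across at least k datasets with an optional protein-domain overlay.
    Includes genome-level orthology summaries, parsers for OrthoFinder-style
    orthogroup tables and InterProScan-style domain annotations, quantitative
    assay helpers (Gompertz dose-response EC50 fitting, broth-microdilution MIC
    calling, delta-delta-Ct relative expression, normalisation to control), and
    a seeded synthetic-data generator (gene-family birth-death simulation on a
    species tree plus planted differential-expression responses) so the whole
    pipeline is testable end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
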