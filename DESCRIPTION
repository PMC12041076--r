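Package: hippotx
Title: Spatial Transcriptomics of the Hippocampal Formation: Cell Typing,
    Percent-Expression Differential Expression, and Spatial Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted in situ sequencing of the mouse
    hippocampal formation. Assigns segmented cells to manually annotated
    regions (CA1-3, dentate gyrus, subgranular layer, entorhinal cortex),
    classifies cells with a divisive hierarchical marker-rule cascade,
    performs percent-expression differential expression by Fisher's exact
    test with Benjamini-Hochberg correction and pseudovalue log2 fold
    changes, scores "restored" genes across genotype/treatment comparisons,
    computes Ripley's K/L spatial clustering curves and cell densities, and
    bins spots for low-dimensional embedding. Includes a synthetic cohort
    generator with ground truth so every stage is testable without the
    original deposit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    methods,
    tools,
    grDevices,
    Matrix,
    jsonlite,
    ggplot2,
    generics,
    sp
Suggests:
    testthat (>= 3.0.0),
    uwot,
    cluster,
    spatstat.geom,
    spatstat.explore,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
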