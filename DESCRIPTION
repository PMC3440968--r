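Package: mirray
Title: Two-Colour miRNA Microarray Analysis for Gender- and
    Stressor-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for two-channel miRNA microarray
    experiments with a crossed gender-by-stressor design, as used to study
    immune and stress responses in the red flour beetle. Covers spot-level
    preprocessing (background subtraction, repeat-probe integration,
    detection calls, MA-LOWESS normalization), per-miRNA t-test contrasts
    with fold-change classification, gender-specific set summaries and Venn
    intersections, average-linkage hierarchical clustering with Newick
    export, per-miRNA two-factor ANOVA, and delta-delta-Ct relative
    quantification of qPCR data. A synthetic-data module emulates the chip
    design and experimental layout with planted ground truth so every stage
    is testable without raw array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
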