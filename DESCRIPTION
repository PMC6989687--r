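Package: ehtmarkers
Title: Marker Discovery for the Endothelial-to-Haematopoietic Transition
    in Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a single-cell RNA-seq analysis
    pipeline that identifies haematopoietic-transitioning cells among
    aorta-gonad-mesonephros (AGM) endothelial cells and nominates surface
    marker genes such as Cd44. Stages: per-cell quality control (mapped-read
    depth and mitochondrial-content filters), spike-in-excluded TPM
    rescaling, PCA on a ten-gene marker panel followed by two-component
    Gaussian-mixture classification anchored on Runx1, a genome-wide
    per-gene likelihood-ratio marker scan with Bonferroni family-wise error
    control, Fisher-exact category enrichment, reporter-metabolite scoring
    over a gene-metabolite network, and Welch's unequal-variance t-test from
    summary statistics. Includes a synthetic-data generator with planted
    ground truth so every stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
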