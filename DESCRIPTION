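Package: cortid
Title: Single-Cell Transcriptomic Identity Analysis for iPSC-Derived
    Cortical Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising induced pluripotent stem cell
    (iPSC)-derived cortical neuron cultures at single-cell resolution.
    Implements the analysis of multiplex single-cell RT-qPCR panels
    (limit-of-detection calling, housekeeper-based well quality control,
    cross-chip batch adjustment, technical-replicate reliability and
    dilution-series linearity checks), marker-panel classification of
    wells into neuronal, GABAergic and glial phenotypes and into deep,
    upper, mixed or unassigned cortical layer identities, permutation
    tests for marker co-expression with Benjamini-Hochberg correction, a
    centroid-distance Wilcoxon test for cluster separation on principal
    components, and the desk-side single-cell RNA-seq computations
    (cell quality-control filters, median-of-ratios size factors, FPKM,
    differential-expression post-filters and pooled-versus-bulk
    correlation). Ships simulators for Ct and count matrices with known
    ground truth plus a deterministic worked-example fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
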