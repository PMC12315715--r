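Package: spectroCell
Title: Hyperspectral Autofluorescence Features Linked to Same-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of per-cell hyperspectral autofluorescence
    imaging and same-cell transcriptomes. Reads and normalizes 15-band image
    stacks, derives per-cell spectral fingerprints, morphology and
    plasma-membrane ring calls from annulus log fold changes, gates cells into
    spectral groups by PCA and kernel density estimation, performs signed
    Kolmogorov-Smirnov differential expression with Benjamini-Hochberg
    correction on CPM-normalized counts, computes per-exon usage fractions and
    Spearman correlations between imaging features and expression or exon
    usage, builds excitation-emission spectra matrices for autofluorescent
    metabolites, and ships seeded simulators of images and negative-binomial
    count matrices with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    SummarizedExperiment,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
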