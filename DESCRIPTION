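Package: tiquant
Title: Brightfield IHC Stain Quantification and Temporal Proteome
    Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies marker expression in brightfield
    immunohistochemistry images by optical-density color deconvolution
    with a fixed hematoxylin/DAB stain basis, threshold binarization,
    Chan-Vese level-set nucleus segmentation and a stained-area to
    nucleus-area (S/N) statistic compared across groups with the
    two-sample Kolmogorov-Smirnov test. Provides the matching temporal
    label-free proteomics cascade: unique-peptide and per-timepoint
    presence filters, median-ratio/glog2 variance-stabilizing
    normalization, left-censored (QRILC-style) imputation,
    empirical-Bayes moderated t differential expression per timepoint,
    and k-means discovery of temporal co-expression modules. Includes
    synthetic-data generators with known ground truth for both input
    families so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    jsonlite,
    optparse,
    tiff,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, DifferentialExpression, CellBasedAssays,
    Clustering, Software
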