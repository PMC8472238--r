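Package: metadereg
Title: Metabolite Deregulation Analysis for Two-Group Untargeted Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-abundance and pathway-deregulation analysis for
    two-group untargeted metabolomics experiments. Provides preprocessing of
    multi-platform feature intensity tables (per-platform median normalization,
    log transformation, mean imputation), empirical-Bayes moderated t-statistics
    with scaled-inverse-chi-square variance shrinkage, Benjamini-Hochberg false
    discovery rate control, a rotation-based (ROAST-style) metabolite-set test
    of pathway deregulation against GMT pathway definitions, and the usual
    descriptive summaries (PCA scores, volcano tables, clustered heatmap
    orderings, group phenotype statistics). A synthetic-data generator with
    hierarchical variances and pathway-coherent effects supports calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
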