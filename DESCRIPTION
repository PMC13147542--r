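Package: mlpquant
Title: Quantification and Genetic Dissection of Multicellular-Like Phenotypes in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring and genetically dissecting multicellular-like
    phenotypes (MLPs) such as surface adhesion and flocculation in fission
    yeast. Quantifies adhesion to agar from pre/post-wash plate scans via
    automatic 96-position grid detection and background-corrected inverse
    pixel intensity; scores flocculation from multi-point plate-reader OD600
    scans using the within-well coefficient of variation; provides screen
    hit-calling statistics (percentile and elbow thresholds, replicate
    confirmation rules, permutation T-tests, Bonferroni and
    Benjamini-Hochberg correction, median-of-ratios count normalization,
    expression-phenotype correlation); calls coding consequences of short
    variants (frameshift, premature stop, truncated protein length) from
    FASTA and GFF3; and maps quantitative trait loci with random-forest
    selection-frequency importance and a permutation null. Ships synthetic
    data generators that produce ground-truth-labelled fixtures for every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    withr,
    png,
    tiff,
    Biostrings,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    ranger,
    jsonlite
Config/testthat/edition: 3
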