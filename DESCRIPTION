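Package: convergene
Title: Genomic Convergence Analysis for Candidate Disease Gene Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a genomic-convergence discovery pipeline for complex
    disease genetics: composite window scoring of GWAS summary statistics and
    merging of flagged windows into association loci, locus-to-gene interval
    mapping, multi-dataset differential-expression convergence with a
    directional-alignment filter and FDR/Bonferroni gates, cis-eQTL overlap
    with Z-score direction interpretation, qPCR 2^-ddCt relative
    quantification with t/rank-sum comparison and ROC validation
    (Hanley-McNeil standard errors), and interaction-network filtering with
    spectral k-means clustering. A seeded synthetic-data generator emulates
    the statistical structure of each input so the whole pipeline runs and is
    testable end-to-end without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
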