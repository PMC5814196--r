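Package: pairmir
Title: Paired Tumor-Normal Differential Expression and miRNA Association
    Analysis for Pathway Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing pathway gene dysregulation
    in paired tumor/normal expression cohorts and its association with miRNA
    expression. Implements reads-per-million-protein-coding-genes (RPMPCG)
    and 75th-percentile scaling normalization, per-gene paired differential
    expression via a negative binomial mixed-effects model with a random
    subject intercept and a log protein-coding-total offset, subject-level
    differential-profile miRNA::mRNA least-squares regression with a
    residual-resampling bootstrap F null distribution, gene-level
    Benjamini-Hochberg false discovery rate control, and miRNA seed-region
    matching (6/7/8 nt seeds) against 3'UTR sequences. A synthetic paired
    cohort generator with planted fold changes, miRNA couplings and seed
    sites supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
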