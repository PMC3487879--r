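Package: eqtlperm
Title: Candidate-SNP eQTL Scans with Permutation-Adjusted P-Values
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for candidate-SNP expression quantitative
    trait locus (eQTL) analysis on expression microarray data:
    detection-P-value probe quality control, quantile normalization of log2
    intensities, removal of age and case/control covariate effects by
    per-probe least squares, per SNP-per transcript linear regression with
    permutation-adjusted P-values, cis/trans classification of variant-gene
    pairs against a distance window, cross-SNP overlap summaries, and local
    gene-set over-representation tests (Fisher exact and EASE) with
    Benjamini-Hochberg FDR. Includes a synthetic-cohort generator with
    Hardy-Weinberg genotypes, planted additive effects of known variance
    fraction, and covariate structure, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    fgsea,
    optparse,
    jsonlite
Config/testthat/edition: 3
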