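Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample, bidirectional Mendelian randomization (MR)
    with two-step mediation analysis, built around GWAS summary statistics.
    Covers instrument selection (p-value threshold, greedy LD clumping,
    variance-explained and F-statistic strength filters), allele
    harmonization between studies, the five standard causal-effect
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    weighted mode, simple mode), heterogeneity and pleiotropy diagnostics
    (Cochran's Q, Egger intercept, an MR-PRESSO-style global/outlier/
    distortion test, leave-one-out), and product-of-coefficients mediation
    decomposition with delta-method intervals. A seeded summary-level
    simulator generates exposure, mediator and outcome GWAS under a known
    structural model so every stage is testable without consortium
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
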