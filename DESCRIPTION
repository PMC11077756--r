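Package: mrmediate
Title: Bidirectional Two-Sample Mendelian Randomization with Mediation
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: instrument selection (genome-wide significance
    filtering, LD clumping, confounder exclusion lists), allele
    harmonization with palindromic-variant handling, instrument strength
    (R-squared and F statistics), univariable estimators (inverse-variance
    weighted, MR-Egger, weighted/simple median, weighted mode), pleiotropy
    diagnostics (Cochran's Q, leave-one-out, simulation-based MR-PRESSO
    global/outlier/distortion tests), multivariable MR with conditional F
    statistics, product-of-coefficients mediation with delta-method
    standard errors, SNP-to-gene annotation via cis-eQTL tables with
    hypergeometric over-representation analysis, and a synthetic
    summary-statistics generator with known causal structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
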