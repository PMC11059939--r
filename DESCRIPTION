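Package: targetmr
Title: Drug-Target Mendelian Randomization with SMR, HEIDI and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization of summary-level
    GWAS data (inverse-variance weighted, MR-Egger, weighted median, mode
    estimators, Cochran's Q, MR-PRESSO), summary-data-based Mendelian
    randomization (SMR) with the HEIDI heterogeneity-in-dependent-instruments
    test, enumeration-based Bayesian colocalization with Wakefield
    approximate Bayes factors, and an end-to-end drug-target screening
    pipeline (instrument selection, LD clumping, allele harmonization,
    confounder and locus-dependence mediation analysis). Includes generators
    for synthetic GWAS and cis-eQTL summary statistics under explicit causal
    architectures so every pipeline stage can be validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
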