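Package: summaryMR
Title: Two-Sample Mendelian Randomization Screening and Mediation from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Causal screening and mediation analysis from GWAS summary
    statistics by two-sample Mendelian randomization. Provides summary-table
    input and allele harmonization, instrument selection (p-value screening,
    greedy LD clumping, F-statistic strength filtering, Steiger
    directionality filtering), five causal estimators (inverse-variance
    weighted fixed and multiplicative random effects, MR-Egger regression,
    weighted median, simple and weighted mode), heterogeneity and
    leave-one-out diagnostics, MR-PRESSO residual resampling with global,
    outlier and distortion tests, product-of-coefficients mediation with
    delta-method standard errors, a many-exposure screening pipeline with
    Benjamini-Hochberg false-discovery control, and a seeded generator of
    synthetic GWAS summary statistics with known ground truth for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
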