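Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: harmonization of exposure and outcome associations
    onto a shared effect-allele convention, selection of genome-wide
    significant LD-independent instruments with per-SNP F statistics,
    univariable estimators (Wald ratio, fixed and multiplicative
    random-effects inverse-variance weighted, weighted median with bootstrap
    standard errors, MR-Egger with its pleiotropy intercept test), a
    simulation-based pleiotropy outlier test with outlier-corrected
    re-estimation (MR-PRESSO), multivariable IVW for direct effects, and
    two-step MR mediation with product-of-coefficients indirect effects,
    delta-method standard errors and mediated proportions. A summary-level
    simulator generates two-sample GWAS statistics under a configurable
    causal chain (exposure, mediator, outcome, pleiotropy) with a
    machine-readable truth record, so every estimator can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
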