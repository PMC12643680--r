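Package: mrmediate
Title: Two-Sample Mendelian Randomization with Product-of-Coefficients
    Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mediating Mendelian randomization of GWAS summary
    statistics: reading and harmonizing summary-association tables,
    instrument selection by p-value threshold, greedy LD clumping and
    F-statistic filtering, six two-sample MR estimators (fixed and
    multiplicative-random-effects IVW, MR-Egger, weighted median, simple
    and weighted mode), heterogeneity and pleiotropy diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO), three-leg pathway
    screening with Benjamini-Hochberg adjustment, and product-of-
    coefficients mediation with delta-method confidence intervals.
    Includes simulators of GWAS summary statistics with known causal
    structure for calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
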