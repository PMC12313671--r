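Package: mrmediate
Title: Two-Sample Mendelian Randomization Screening and Two-Step Mediation
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: allele harmonization of exposure and outcome
    tables, instrument selection (genome-wide p-value threshold with a
    relaxed fallback, greedy LD clumping, minor-allele-frequency and
    instrument-strength filters, Steiger directionality filtering), six
    causal-effect estimators (Wald ratio, inverse-variance weighted,
    maximum likelihood, MR-Egger, weighted median, and mode-based
    estimators), sensitivity diagnostics (Cochran's Q, Egger intercept,
    MR-PRESSO global/outlier/distortion tests, leave-one-out), batch
    screening of many exposures against one outcome with
    Benjamini-Hochberg false-discovery-rate control, and two-step MR
    mediation analysis with delta-method confidence intervals.  A
    summary-statistic simulator with known ground truth (causal chains,
    pleiotropic and reverse-causal instruments, block LD) supports
    calibration studies of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
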