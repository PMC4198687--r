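Package: cohenh
Title: Cohen's h Effect Sizes, Tests and Power for Rare-Variant
    Case-Control Association
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-marker case-control association analysis of biallelic
    variants on the allele scale, centred on Cohen's h -- the effect size
    obtained from the arcsine square-root (variance-stabilizing)
    transformation of minor-allele frequencies. Provides estimators and
    asymptotic tests for the risk difference, Cohen's h and the allelic
    odds ratio, a Fisher exact-test fallback for extremely rare alleles,
    analytic power and sample-size calculators for the two-proportion and
    Cohen's h tests at genome-wide significance levels, effect-size
    classification thresholds calibrated for rare and common variants,
    SNP-level quality-control filters (minor-allele frequency, call rate,
    Hardy-Weinberg exact test, control-cohort heterogeneity), and
    Monte-Carlo machinery for null calibration (bias, mean squared error,
    type I error) and empirical power under Hardy-Weinberg binomial
    sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
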