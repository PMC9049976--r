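Package: clockmr
Title: Two-Sample Mendelian Randomization for Epigenetic Age Acceleration
    and Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    studying the genetically predicted effects of epigenetic age acceleration
    (HannumAge, Intrinsic HorvathAge, PhenoAge, GrimAge) on cancer risk from
    GWAS summary statistics. Covers reading and validating summary statistics,
    allele harmonisation with palindromic-SNP frequency alignment, instrument
    selection (genome-wide significance, greedy LD clumping, proxy
    substitution) and strength diagnostics (per-SNP R-squared and
    F-statistics), the estimator suite (Wald ratio, fixed and multiplicative
    random-effects inverse-variance weighting, MR-Egger, weighted median,
    weighted mode), single-SNP and leave-one-out analyses, Steiger
    directionality testing and filtering, fixed-effect meta-analysis across
    studies with I-squared and test-based confidence intervals, per-SNP GWAS
    meta-analysis, Benjamini-Hochberg false-discovery-rate control with a
    configured family size, binary-outcome MR power calculation with
    minimum-detectable odds-ratio inversion, and a calibrated synthetic
    summary-statistics generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    readr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
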