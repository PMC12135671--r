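Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) mediation
    analysis from GWAS summary statistics: reading, validation and effect-allele
    harmonization of summary-statistics files; instrument selection by
    genome-wide significance, greedy linkage-disequilibrium clumping and
    F-statistic screening; univariable MR estimation with fixed-effect and
    multiplicative-random-effects inverse-variance weighting, MR-Egger,
    weighted-median and MR-PRESSO estimators plus Cochran's Q and Egger
    intercept diagnostics; multivariable MR by inverse-variance weighting;
    two-step mediation with delta-method confidence intervals and mediator
    screening; and a summary-statistics simulator with known ground truth for
    end-to-end validation.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
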