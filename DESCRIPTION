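Package: mrscreen
Title: Two-Sample Mendelian Randomization Screens from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization from
    GWAS summary statistics: instrument selection and quality control
    (genome-wide significance threshold, greedy linkage-disequilibrium
    clumping, confounder exclusion lists, F-statistic filtering), allele
    harmonization with palindromic-variant handling, five causal-effect
    estimators (Wald ratio, inverse-variance weighted with fixed or
    multiplicative random effects, MR-Egger, weighted median, maximum
    likelihood), sensitivity diagnostics (Cochran's Q, Egger intercept,
    Steiger directionality), cross-cohort meta-analysis (fixed effect and
    DerSimonian-Laird) with Bonferroni multiple-testing control, and a
    synthetic summary-statistics generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
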