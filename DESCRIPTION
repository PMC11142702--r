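Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for two-sample Mendelian randomization (MR) on GWAS
    summary statistics: instrument selection and quality control (LD
    clumping, F-statistics, Steiger directionality filtering, proxy
    substitution, allele harmonization), univariable causal estimators
    (Wald ratio, multiplicative random-effects IVW, MR-Egger, weighted
    median, constrained maximum likelihood), sensitivity diagnostics
    (Cochran's Q, Egger intercept, MR-PRESSO, leave-one-out),
    multivariable MR and two-step mediation with proportion mediated,
    cis-instrument drug-target MR over gene windows, approximate-Bayes-
    factor colocalization, cross-dataset meta-analysis with an I-squared
    model rule, Benjamini-Hochberg false-discovery-rate correction, and
    analytic power for binary outcomes.  A synthetic summary-statistics
    generator with known causal truth makes the whole pipeline testable
    without external downloads.
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
    testthat (>= 3.0.0),
    metafor,
    optparse,
    withr
Config/testthat/edition: 3
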