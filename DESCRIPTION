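Package: neuromr
Title: Two-Sample Mendelian Randomization for GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit built
    around GWAS summary statistics: instrument selection (p-value filtering,
    greedy LD clumping, F-statistic screening), allele harmonization with
    palindrome handling, univariable causal estimation (inverse-variance
    weighted with multiplicative random effects, MR-Egger, weighted median),
    sensitivity diagnostics (Cochran's Q, Egger intercept, leave-one-out,
    funnel data, MR-PRESSO global and outlier tests), multivariable MR, and
    two-step mediation MR with the proportion mediated by product of
    coefficients. Includes a synthetic GWAS summary-statistics generator with
    known causal and mediation structure so every stage of the pipeline is
    verifiable at desk scale, and a study driver that orchestrates an
    exposure-by-outcome grid with Bonferroni multiplicity control and
    pleiotropy-based dismissal.
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
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
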