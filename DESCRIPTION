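Package: episnp
Title: Two-Locus SNP Interaction Analysis for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-locus association and two-locus gene-gene interaction
    analysis for biallelic SNPs in case-control designs. Implements
    genotype odds-ratio profiling against a non-risk reference genotype,
    Breslow-Day homogeneity tests of odds ratios, relative excess risk due
    to interaction (RERI) with MOVER confidence intervals and stratified
    bootstrap p-values, Cordell-Clayton genotypic interaction by logistic
    regression (additive and dominance codings), exact Hardy-Weinberg
    equilibrium tests, and a retrospective case-control cohort simulator
    with known penetrance for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
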