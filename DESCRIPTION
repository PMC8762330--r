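Package: poolburden
Title: Gene-Based Rare-Variant Burden Testing for Pooled DNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Gene-based association testing of rare and low-frequency variants
    called from pooled DNA sequencing, where only per-pool maximum-likelihood
    alternative-allele counts (MLAC) are observable. Provides call-level quality
    control (QUAL filtering, per-pool allele-fraction noise zeroing, MLAC
    estimation), seven qualifying-variant filters combining functional class,
    in-silico damaging consensus, regulatory overlap and minor-allele-frequency
    cutoffs, pool-adapted weighted-sum (WSS) burden and C-alpha
    variance-component statistics with pool-label permutation nulls, a
    Fisher-combined hybrid test sharing one permutation set, fixed-effect
    inverse-variance meta-analysis of per-variant odds ratios, random-effect
    standardized-mean-difference meta-analysis, and a synthetic pooled-cohort
    generator for calibration, power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
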