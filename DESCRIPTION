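Package: pooldisp
Title: Extra-Binomial Association Tests for Pooled Case-Control Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association testing for case-control DNA sequencing of pooled
    samples, where allele read counts are over-dispersed relative to the
    binomial because pools of finite chromosome number, PCR and sequencing
    all add variance. Implements an extra-binomial test (EB2) whose variance
    function is governed by two global over-dispersion parameters estimated
    by regression across SNPs, the per-SNP quasi-likelihood comparator of
    Williams (EB1), and the naive Fisher's exact baseline on estimated
    chromosome counts, together with the SNP/pool filtering pipeline
    (minimum depth, MAF partition, random-error screen with Bonferroni
    correction, chromosome-coverage occupancy filter), base-specific
    sequencing error-rate estimation and count correction, a pooled-design
    simulator with truth labels, and Q-Q / Type-1-error / power evaluation
    machinery. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
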