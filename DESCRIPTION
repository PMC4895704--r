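Package: repower
Title: Empirical Bayes Power Estimation and Sample Size Determination for
    GWAS Replication Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for designing replication studies of case-control
    genome-wide association studies from primary-study summary statistics
    alone.  Implements per-SNP Bayesian predictive power under a
    two-component mixture prior on log-odds ratios, which corrects the
    winner's curse affecting naive plug-in power estimates; conditional
    maximum likelihood and Empirical Bayes effect-size corrections for
    comparison; credible intervals for per-SNP and average power via
    combined Monte Carlo and bootstrap sampling; local true discovery rate
    weighted average power; and replication sample-size determination.
    Includes a two-stage case-control GWAS simulator with mixture
    effect-size models and an experiment harness for bias, RMSE and
    interval-coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
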