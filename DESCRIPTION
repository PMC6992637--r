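Package: actimr
Title: Two-Sample Mendelian Randomisation for Accelerometer-Measured
    Physical Activity and Cancer Risk
Version: 1.0.0
Authors@R:
    person("actimr", "developers", email = "actimr@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation (MR) with GWAS
    summary statistics, built around the genetic instruments for
    accelerometer-measured physical activity and binary cancer outcomes.
    Provides summary-statistic input/output and allele harmonisation,
    instrument strength metrics (per-variant R-squared and F-statistics),
    a priori power for binary outcomes, inverse-variance weighted,
    MR-Egger and weighted-median causal estimators with Cochran's Q and
    I-squared heterogeneity statistics, MR-PRESSO outlier detection,
    leave-one-SNP-out and multivariable MR diagnostics, a seeded
    generator of synthetic two-sample GWAS datasets with known truth,
    and a pipeline applying Benjamini-Hochberg false-discovery-rate
    correction across an analysis grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
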