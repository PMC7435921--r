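Package: vfegm
Title: Spectral and Information-Theoretic Analysis of Paired Ventricular
    Fibrillation Electrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing simultaneously recorded left- and
    right-ventricular electrograms during ventricular fibrillation.
    Provides Welch-periodogram spectral parameters (fundamental and
    dominant frequency, harmonic peak powers, mean frequency, 75%
    bandwidths, organization index, leakage), histogram-based
    differential entropy, joint entropy and mutual information with
    bin-width and sample-size bias diagnostics, paired cohort
    statistics, and a synthetic-data module that generates bivariate
    Gaussian validation sets and VF-like paired signals with known
    ground truth so the whole pipeline is testable without patient
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
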