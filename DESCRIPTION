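Package: sidcor
Title: Signed and Partial Distance Correlation Networks for Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes signed distance correlation between features of a
    samples-by-features omics matrix, in one-to-one and one-to-all modes,
    with Student-t based p-values and companion Pearson and Spearman
    statistics. Partial distance correlations are obtained by pseudo-inverting
    the distance-covariance matrix (the Gaussian graphical model route) with
    Fisher-z p-values. Includes a seeded synthetic-data generator with known
    dependence structure, threshold-based edge filtering, and a command-line
    pipeline that reads CSV or XLSX tables and writes network-ready CSV edge
    lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    readr,
    readxl,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
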