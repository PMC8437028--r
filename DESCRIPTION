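Package: poolsel
Title: Genotype-Dependent Mortality from Pooled Allele-Frequency Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of viability selection in pooled larval cohorts from
    allele-count time series. Implements count-table filtering, per-locus
    binomial generalized linear model tests of allele-frequency change with
    Benjamini-Hochberg correction, parametric categorization of change
    patterns via sequential Tukey comparisons, k-means clustering of
    allele-frequency-change trajectories, in-silico factorial-cross
    estimation of egg-pool genotype composition, rejection-sampling
    reconstruction of genotype-frequency and fitness trajectories under a
    Hardy-Weinberg fitness model, Hardy-Weinberg distortion analysis of the
    settled-juvenile stage, and linkage-map bridging of markers. Includes a
    synthetic-data generator with known genotype-dependent mortality so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
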