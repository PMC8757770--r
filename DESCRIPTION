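Package: cddmcascade
Title: Two-Stage Classification of Myocardial Current Density Distribution Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies magnetocardiographic current density distribution maps
    (CDDMs) into 14 heart-state groups with a two-stage cascade. Stage one ranks
    groups by the resulting correlation coefficient (the product of the Pearson
    correlations of the magnitude and direction vectors against a labelled
    reference set, aggregated as the mean of the m largest values per group). A
    rule engine encoding empirically confusable group pairs decides whether the
    top-ranked group must be re-adjudicated; if so, stage two runs a pairwise
    k-nearest-neighbour duel on 32 quadrant statistical-moment features
    (mean, variance, kurtosis, skewness of magnitude and angle per quarter)
    under a per-pair distance metric and neighbour count. Includes a seeded
    synthetic cohort generator, a balanced repeated-holdout evaluation harness
    with one-vs-all metrics, a metric-by-k parameter sweep, and a command-line
    interface.
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
    withr,
    jsonlite
Config/testthat/edition: 3
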