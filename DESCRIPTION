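Package: resurvey
Title: Temporal Beta-Diversity and Trait Analysis of Resurveyed Point-Quarter Forest Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing repeated point-centred-quarter surveys of permanent
    forest grids: ingestion and validation of survey records, cohort splitting and
    fishnet cell construction, subsampled significance testing of species and guild
    change (paired Wilcoxon and t tests over grid-point subsamples), Hellinger-distance
    beta-diversity machinery (multivariate dispersion test for biotic homogenization,
    PERMANOVA, principal coordinates analysis, LCBD/SCBD partitioning with temporal
    differences, replacement versus richness-difference components), community-weighted
    mean trait change, and a synthetic two-period resurvey generator for calibration and
    power experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
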