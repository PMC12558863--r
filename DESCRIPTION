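Package: actiphen
Title: Rest-Activity Rhythm Phenotyping from Minute-Level Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for phenotyping rest-activity rhythms from minute-level
    wrist actigraphy (MIMS-style activity values). Recordings are screened
    for robust 24-hour periodicity via smoothed-autocorrelation peak spacing
    and a chi-square consistency test, compressed into per-subject "average
    day" profiles, clustered within age groups by k-means with
    curvature-based selection of the number of clusters, and summarized by a
    two-level piecewise-constant model yielding sleep-onset and wake-time
    proxies together with derivative-based markers (winding-down period and
    activity, overall activity, time to alertness). Marker distributions are
    compared between groups with weighted 1-Wasserstein distances and
    permutation tests. A seeded synthetic-cohort generator with known ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
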