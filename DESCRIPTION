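Package: twinconn
Title: Twin-Based Heritability of Static and Dynamic Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the heritability of static and dynamic functional
    connectivity phenotypes from twin-pair cohorts. Builds edge-level
    connectivity phenotypes (static correlation, sliding-window dynamic
    mean and variance, and task-contrast differences) from ROI time
    series, fits ACE/ADE/AE/E variance-component models to monozygotic
    and dizygotic twin pairs by maximum likelihood, decomposes windowed
    connectivity into recurring network states with occupancy and dwell
    metrics, and ships a synthetic twin-cohort generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
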