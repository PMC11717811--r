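Package: astromigr
Title: Quantification of Postnatal Astrocyte Progenitor Migration Assays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying postnatally migrating astrocyte
    progenitors in fluorescence microscopy experiments: per-cell marker
    colocalization scoring on segmented label masks (whole-cell, membrane
    "donut", and nuclear regions), implant-centered migration geometry for
    organotypic explant assays (net/lateral/radial displacement, speed,
    distance into cortex past a smoothed white-matter curve, automated
    migrated-cell counting), log-scale linear mixed models with nested
    litter/slice random effects and a family-gated F-then-Wald testing
    procedure, paired t-test power calculations, and the single-cell RNA-seq
    QC, log-normalization and cluster-marker statistics used alongside the
    imaging assays. Includes seeded synthetic-data generators with attached
    ground truth for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    Matrix,
    methods,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
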