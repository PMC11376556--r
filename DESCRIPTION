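Package: tcdiverge
Title: Cross-Group Time-Course Divergence Scoring for Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how differently two groups (for example, two species'
    fibroblast lines under oxygen deprivation) respond over a shared time
    course, layer by layer (RNA counts, protein intensities). Curves are
    anchored at the baseline time point as log2 ratios; each ortholog pair is
    scored with score = (1 - |A|) * B, where A is the Pearson correlation
    between the two groups' temporal response curves and B is the absolute
    area between their piecewise-linear interpolants. The package adds
    percentile flagging of high-divergence pairs, per-timepoint differential
    calls with Benjamini-Hochberg control, Ward clustering of temporal
    profiles, cross-layer overlap through a one-to-one ortholog map,
    Fisher's exact set enrichment, and a seeded synthetic-data generator
    with planted temporal archetypes and truth labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
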