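Package: tampor
Title: Tunable Median Polish of Ratio for Batch Correction of Omics Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Batch-effect correction and multi-cohort/multi-platform
    harmonization of nonnegative feature-by-sample abundance matrices
    (proteomics, metabolomics, censored transcriptomics) by a tunable,
    iterative median polish of ratios.  Denominators may use global
    internal standard (GIS) bridging channels, all samples per batch, or a
    GIS-plus-non-GIS batch factor that tolerates defective bridging
    standards.  Includes pre-correction filters, quality-control metrics
    (mean-SD series, classical multidimensional scaling, per-feature
    variance partition, biweight midcorrelation, replicate-pair and
    all-pair correlation-shift analyses, differential abundance), a seeded
    synthetic-data generator with ground truth for benchmarking, and a
    command-line interface.
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
    optparse
Config/testthat/edition: 3
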