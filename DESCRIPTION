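Package: geomxnorm
Title: Quality Control, Normalization Benchmarking and Co-Expression
    Networks for GeoMx DSP Probe Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for NanoString GeoMx Digital Spatial
    Profiler probe-level count data: probe- and ROI-level quality
    filters, geometric-mean target collapse, per-ROI limit of
    quantification (LOQ) and signal-to-noise statistics, five
    normalization methods (third-quartile, modified CPM,
    median-of-ratios, gamma-fit correction, quantile), a benchmarking
    framework that quantifies the group-differential signal-to-noise
    bias and its removal, median-based differential expression with
    Wilcoxon rank-sum tests, and a lightweight signed weighted
    co-expression network analysis with module eigengenes and trait
    correlations. Includes a negative-binomial probe-count simulator
    with planted differential expression, a trait-correlated module,
    and group-differential background so every stage is testable
    without external data.
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
    withr,
    MASS,
    limma,
    DESeq2,
    optparse
Config/testthat/edition: 3
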