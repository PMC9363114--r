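Package: photoduet
Title: Dual-Sensor Fiber Photometry Analysis of Striatal Dopamine and
    Acetylcholine Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously recorded dual-sensor
    fiber-photometry signals, built around paired striatal dopamine
    (dLight-type) and acetylcholine (GRAB-ACh-type) recordings with 465 nm
    signal and 405 nm isosbestic control channels. Provides
    isosbestic-regression motion correction and dF/F computation,
    event-aligned trial extraction with local baseline subtraction,
    quantification of the acetylcholine dip (amplitude, zero-crossing
    duration, negative/rebound/total area under the curve) and the dopamine
    peak, lagged Pearson cross-correlation of the paired signals with
    extremum identification, behavioral-latency coupling analysis, one-way
    repeated-measures ANOVA with Greenhouse-Geisser correction, and the
    partial eta-squared / Cohen's f / noncentral-F sample-size chain.
    Includes a seeded generator of synthetic dual-sensor sessions with
    complete ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
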