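Package: avalanchr
Title: Neuronal Avalanche Statistics from Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for neuronal-avalanche statistics in
    two-photon calcium-imaging recordings of auditory cortex: conversion of
    raw fluorescence to neuropil-corrected dF/F, binarization of
    spike-probability rasters with an ensemble-count-maximizing threshold,
    extraction of neuronal ensembles (avalanches) and per-neuron temporal
    shuffle nulls, discrete power-law versus exponential model selection by
    maximum likelihood and Kolmogorov-Smirnov slope estimation, scaling
    collapse of size distributions across sound levels, and ensemble
    receptive-field tuning metrics (best frequency, IQR of best
    frequencies, bandwidth). Includes seeded synthetic-data generators
    (critical branching rasters, truncated discrete power-law samplers,
    tone-tuned populations, surrogate fluorescence) so the full pipeline is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
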