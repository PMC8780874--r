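Package: aquaNIR
Title: NIR Spectroscopy and Aquaphotomics Toolkit for Two-Component
    Blend Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric analysis of near-infrared (NIR) absorbance
    spectra of two-component blends, with coffee (Arabica adulterated
    with Robusta) as the motivating application. Provides an S4
    container for spectra with hierarchical sample metadata, a
    synthetic mixture-spectra generator (linear Beer-Lambert mixing of
    Gaussian-peak endmembers with scatter, drift and noise), the
    standard NIR preprocessing toolbox (truncation, Savitzky-Golay
    smoothing and derivatives, multiplicative scatter correction,
    standard normal variate, detrend, hierarchical averaging),
    principal component analysis, hybrid PCA-LDA classification with
    grouped cross-validation and confusion-matrix reporting, NIPALS
    partial least squares regression of the adulterant mass fraction
    with grouped and leave-group-out cross-validation, and classical
    aquagram (water absorption spectral pattern) computation at the
    water matrix coordinate wavelengths of the first and second
    overtone regions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'SpectraSet-class.R'
    'models-classes.R'
    'aquaNIR-package.R'
    'io.R'
    'synth.R'
    'preprocess.R'
    'pca.R'
    'cv.R'
    'plsr.R'
    'classify.R'
    'aquagram.R'
    'pipeline.R'
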