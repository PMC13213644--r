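Package: rootspec
Title: Hyperspectral Chemometrics for Authentication of Medicinal Root Material
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A visible/near-infrared hyperspectral imaging workflow for
    authenticating medicinal root material (tuberous root, taproot, old
    root) and quantifying marker constituents. Covers dark/white
    reflectance calibration of ENVI-style hypercubes, region-of-interest
    spectrum extraction, spectral pre-processing (standard normal variate,
    Savitzky-Golay smoothing and derivatives), effective-wavelength
    selection (competitive adaptive reweighted sampling, successive
    projections algorithm with SPXY partitioning, random frog),
    classification (logistic regression, support vector machine,
    multi-layer perceptron) and quantitative calibration (least-squares
    support vector machine, extreme learning machine, back-propagation
    neural network), standard chemometric evaluation metrics, pixel-wise
    concentration mapping, and a metabolomics differential-feature screen
    (occurrence/response filtering, ANOVA plus fold-change, PCA, PLS-DA,
    hierarchical clustering). Ships a synthetic-data generator emulating
    the three root classes and three marker analytes so the whole pipeline
    runs without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    MASS,
    nnet,
    e1071,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
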