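Package: hemospec
Title: Hyperspectral Bloodstain Identification by Derivative Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for identifying dried bloodstains in
    visible/near-infrared hyperspectral images (397-1003 nm, 224 bands).
    Covers empirical-line reflectance calibration from dark/white reference
    captures, region-of-interest extraction at 540 nm, spectral
    pre-treatments (SNV, MSC, Savitzky-Golay smoothing), the Savitzky-Golay
    second-derivative transform that enhances the hemoglobin alpha/beta
    absorption bands, derivative-based band selection (470-770 nm),
    classification with standard machine-learning families, and a full
    evaluation suite (confusion matrix, overall accuracy, Cohen's kappa,
    precision, sensitivity, specificity, F1) under sample-based and
    pixel-based train/test splitting. Because real casework hypercubes are
    rarely shareable, the package includes a synthetic hypercube generator
    that emulates hemoglobin spectral physics (Soret/alpha/beta bands,
    hemichrome/methemoglobin 600-650 nm slope, three-day aging, donor
    baseline shifts) and eight red confuser substances on three substrates,
    with ENVI-format input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    e1071,
    randomForest,
    rpart,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    class,
    signal,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
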