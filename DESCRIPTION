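Package: msppca
Title: Probabilistic PCA and SVM Classification for SELDI-TOF Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for early-cancer-detection analysis of SELDI-TOF mass
    spectra: spectrum input/output, a preprocessing chain (resampling onto a
    uniform m/z grid, running-minimum baseline correction, wavelet or
    moving-average denoising, cross-correlation peak alignment, total-ion-current
    normalization), probabilistic principal component analysis fitted by
    expectation-maximization or by the closed-form eigendecomposition solution,
    RBF-kernel support vector machine classification with cross-validated grid
    search, and a repeated stratified hold-out evaluation protocol reporting
    accuracy, sensitivity, specificity and ROC/AUC. A synthetic spectrum
    simulator with class-dependent peaks makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'classify.R'
    'data-reference.R'
    'endtoend.R'
    'evaluate.R'
    'msio.R'
    'msppca-package.R'
    'ppca.R'
    'preprocess.R'
    'synthspec.R'
    'utils.R'
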