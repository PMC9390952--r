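Package: glngca
Title: Group Linear Non-Gaussian Component Analysis for Multi-Subject Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-stage group linear non-Gaussian component analysis (group
    LNGCA) for multi-subject imaging data such as resting-state fMRI.
    Stage one extracts each subject's non-Gaussian spatial components by a
    fixed-point algorithm maximizing the logistic (Infomax) non-linearity
    after pre-whitening; stage two recovers spatial components shared
    across subjects via a singular value decomposition of the concatenated
    unit-norm subject components followed by noise-free ICA, and estimates
    subject-specific components in the orthogonal complement.  Includes a
    resampling test (FOBI with a spatially correlated Gaussian random
    field null) for the number of non-Gaussian components per subject, a
    temporal-concatenation PCA+ICA baseline, Hungarian matching of
    components against references, a log-variance engagement test, NIfTI
    input utilities, and a synthetic multi-subject study generator with
    AR(1) mixing and controlled subspace variance allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    graphics,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
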