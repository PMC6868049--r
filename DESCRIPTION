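Package: rfradiomics
Title: Radiomics on Parametric Feature Maps from Ultrasound Radio-Frequency Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-ultrasound radiomics pipeline operating on raw
    radio-frequency (RF) echo data in scan-line representation. Provides a
    seeded synthetic RF cohort generator with controllable attenuation,
    Nakagami envelope statistics and local spectral heterogeneity; B-mode
    formation (Hilbert envelope, log compression) and marker-based ROI
    segmentation; sliding-window parametric feature maps (direct energy
    attenuation, Nakagami omega, standard deviation of spectrum difference);
    a 70-feature texture battery (histogram, GLCM, GLRLM, GLSZM, NGTDM)
    replicated over one-level Haar wavelet sub-bands; iterative
    sparse-representation feature ranking; and SVM classification with
    leave-one-out cross-validation, ROC/PRC and decision-curve evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    pROC,
    jsonlite,
    png,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
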