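Package: bdatr
Title: Bi-Directional Axial Transmission Ultrasound for Cortical Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and inversion of bi-directional axial
    transmission (BDAT) ultrasound measurements of cortical bone, together
    with the clinical statistics used to evaluate them. Provides a guided-wave
    (Lamb-mode) dispersion solver for a porosity-parametrized transversely
    isotropic plate, a multichannel array-signal synthesizer, the SVD-based
    Norm function (f-k guided-wave spectrum), the Proj inversion of cortical
    thickness and porosity, first-arriving-signal and A0 velocimetry with the
    four-series measurement protocol, a Gaussian-copula synthetic patient
    cohort generator, and partial-least-squares fracture-discrimination
    analyses with leave-one-out cross-validation, logistic odds ratios and
    ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Matrix,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
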