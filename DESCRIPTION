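Package: stripeqmri
Title: Columnar Structure-Function Analysis of Quantitative MRI in Visual
    Cortex Stripes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer differential myelination of human V2
    cytochrome-oxidase stripe types from surface-sampled quantitative MRI
    (R1, R2*, PD) and columnar fMRI localizers. Provides functional stripe
    ROI construction by z-score thresholding with overlap exclusion,
    curvature-deconfounded stripe-versus-rest contrasts, spatial
    autocorrelation preserving (variogram-matched) surrogate maps for
    permutation inference with a binomial three-sigma correction, multi-echo
    dual flip angle FLASH relaxometry (ESTATICS R2* fitting, rational Ernst
    approximation R1/PD with B1+ correction, white-matter PD calibration),
    equi-volume cortical depth sampling, phase-encoded retinotopy analysis,
    and a synthetic cortical-patch cohort generator so the full pipeline is
    testable without scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
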