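Package: thyrotex
Title: Texture-Based Stratification of Thyroid Nodules on Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for preoperative stratification of thyroid nodules from
    two-b-value diffusion-weighted MRI. Computes noise-rectified apparent
    diffusion coefficient (ADC) maps and area-weighted nodule ADC means,
    extracts a MaZda-style catalogue of more than 250 named texture features
    (gray-level co-occurrence, run-length, histogram, gradient,
    autoregressive, Haar-wavelet and geometric families) over regions of
    interest, reduces features by Fisher coefficient, mutual information and
    POE+ACC ranking followed by backward elimination against linear
    discriminant misclassification, classifies slices by the first
    discriminant score (MDF1) against a trained cutoff, aggregates slice
    calls to nodule calls by the lowest-scoring-slice rule, and evaluates
    with ROC/AUC, exact binomial confidence intervals and Welch t tests.
    A seeded synthetic cohort generator emulates the class-conditional ADC
    and texture structure of benign and malignant nodules so the full
    pipeline is testable without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    MASS,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
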