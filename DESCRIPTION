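Package: wsisurv
Title: Patient-Level Deep Survival and Biomarker Modeling from Whole-Slide Image Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for predicting right-censored survival and a
    binary somatic biomarker (IDH mutation status) from whole-slide histology
    images. Slides are cut into fixed-size tiles with background exclusion by
    color thresholding; a small convolutional backbone embeds each tile, patch
    embeddings are average-pooled per patient, and a fully connected head
    produces a risk score trained with the negative log Cox partial likelihood
    (or weighted cross-entropy for classification). Block-stratified repeated
    train/validation/test splits provide pooled out-of-sample predictions,
    and bootstrap resampling compares Cox and logistic models fit with and
    without the image-derived scores. A synthetic histology and survival
    cohort generator with known latent risk makes every stage testable on a
    single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    Matrix,
    png,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
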