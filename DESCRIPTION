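Package: dermfuse
Title: Dermoscopy Lesion Multiclassification by Fused Handcrafted and Deep Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for multiclass skin-lesion
    classification from dermoscopy images: speckle denoising with a modified
    anisotropic diffusion filter whose stopping rule tests the Gaussianity
    (excess kurtosis) of the multiplicative noise residual; grey-level
    histogram clustering segmentation of the lesion; histogram-of-oriented-
    gradients descriptors fused with a VGG19-style deep feature tap;
    entropy-based feature selection; SMOTE-Tomek class rebalancing; and a
    softmax classifier head with full evaluation statistics (confusion matrix,
    macro precision/recall/F1, one-vs-rest AUC, one-way ANOVA). Includes a
    seeded generator of dermoscopy-like synthetic lesion images so every stage
    is exercisable without any external download, and Grad-CAM saliency maps
    for the deep backbone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
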