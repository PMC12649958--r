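Package: fundusXAI
Title: Saliency-Map Evaluation for Fundus-Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A model-agnostic framework for generating and evaluating
    saliency-map explanations of diabetic-retinopathy grading models.
    Implements seven attribution methods (Gradient, SmoothGrad, Integrated
    Gradients, expected-gradients SHAP, DeepLIFT-Rescale, Grad-CAM++ and
    ScoreCAM), a pixel-flipping perturbation protocol with AOPC scoring,
    saliency entropy, and lesion-mask overlap metrics (Recall, Dice), together
    with a lesion-insertion trend-correlation experiment. Ships a synthetic
    fundus-scene generator with exact lesion masks and fixture classifiers with
    known decision structure, so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
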