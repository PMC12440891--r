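Package: dscseg
Title: Lightweight Encoder-Decoder Semantic Segmentation for Crop/Weed Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lightweight DeepLabv3+-style semantic segmentation stack for
    separating maize seedlings, weeds and soil in overhead field imagery.
    Implements a MobileNetV2 backbone, depthwise separable dilated
    convolutions, a strip-pooling atrous spatial pyramid pooling head,
    convolutional block attention and an attention-recalibrated cascade
    feature fusion decoder, together with Pascal-VOC-layout dataset I/O, a
    sixfold augmentation suite, a seeded synthetic field-scene generator, an
    SGD training schedule with a frozen-backbone phase, mean-IoU evaluation
    and an exact parameter/multiply-accumulate profiler.  All forward and
    backward passes are implemented in the package (R with C++ convolution
    kernels), so every architectural claim is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    jpeg
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
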