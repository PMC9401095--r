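Package: ratcapsnet
Title: Dual-Pipeline Attention Network for Wireless Capsule Endoscopy Abnormality Detection
Version: 0.1.0
Authors@R: person("WCE", "Imaging Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a convolutional classifier for wireless capsule endoscopy
    (WCE) frames built from two bespoke blocks: a Volumetric Attention Mechanism
    (VAM) that condenses a feature map spatially and channel-wise into a
    single-channel sigmoid mask used for residual enhancement, and a Pyramid
    Feature Extractor (PFE) that encodes local regional correlations through
    parallel multi-scale convolutions with successive fusion. Includes the
    smallest-class-referenced train/validation split with augmentation-based
    upsampling for heavily imbalanced class structures, confusion-count metrics
    (precision, recall, F1, accuracy with macro averaging), a seeded synthetic
    WCE image generator for framework-free testing, training/evaluation loops
    with Adam, attention-mask visualization, and a command-line interface.
    All tensor operations (convolution, depthwise and transposed convolution,
    pooling) and backpropagation are implemented natively via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jpeg
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
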