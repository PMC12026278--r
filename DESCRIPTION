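Package: foodseg
Title: Lightweight Semantic Food Segmentation with Complexity Profiling,
    Conformal Uncertainty and Nutrient Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A lightweight encoder-decoder for semantic segmentation of food
    plates: an EfficientNet-B1 backbone tapped at strides 4 and 16, a
    cascaded-waterfall atrous pooling neck, a registry of channel-attention
    heads (squeeze-and-excitation and alternatives) and the DeepLabv3+
    decoder, implemented natively with hand-written forward and backward
    passes. Ships the full training recipe (SGD with momentum, polynomial
    learning-rate decay, random horizontal flips), per-image mean-IoU
    evaluation, an exact parameter and multiply-accumulate profiler with
    Pareto-frontier analysis, post hoc conformal-prediction uncertainty
    heatmaps, and mask-based estimation of grams, energy, protein and
    carbohydrate from plate-area proportions. A deterministic synthetic
    plate-scene generator makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
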