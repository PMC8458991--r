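Package: coarse2fine
Title: Coarse-to-Fine Spatial-Frequency Curriculum Training for Image
    Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying coarse-to-fine visual learning in
    convolutional image classifiers. Implements calibrated Butterworth
    low/high-pass filtering of images specified in cycles per degree of
    visual angle, the full/gradual/mixed spatial-frequency curriculum
    training regimes, hybrid (low/high-pass composite) stimulus
    construction, per-frequency-level accuracy evaluation with binomial
    confidence intervals, and representational similarity analysis with
    permutation and bootstrap inference. A seeded synthetic
    shape-plus-texture image generator and a small pure-R convolutional
    classifier make the whole pipeline runnable at desk scale without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Classification, Visualization
RoxygenNote: 7.3.3
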