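Package: payloadSPT
Title: Single-Particle Tracking Analysis of Fluorescent Payload Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cytosolic delivery of fluorescent
    payloads from two-channel live-cell time-lapse microscopy by
    single-particle tracking. Provides a synthetic microscopy simulator
    (four diffusion modes including fractional Brownian subdiffusion,
    pixel-integrated Gaussian point-spread-function rendering, shot and
    read noise), difference-of-Gaussians spot detection with subpixel
    centroids and shape descriptors (radius of gyration, eccentricity),
    optimal-assignment trajectory linking, time-averaged mean-squared
    displacement and anomalous-exponent fitting, rule-based diffusion-mode
    segmentation (normal, directed, confined, subdiffusive), membrane
    residence and delivery-path classification, and population statistics
    (Kolmogorov-Smirnov and Welch tests, Pearson and Manders
    colocalization).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
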