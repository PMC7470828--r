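Package: calciscope
Title: Calcium-Imaging Responder Classification and RNAscope Dot
    Quantification for Sensory-Neuron TRP-Channel Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification of TRP-channel function and
    expression in dorsal root ganglion neurons and cutaneous nerve
    endings. Implements preprocessing of GCaMP time-lapse movies
    (z-averaging, translational drift correction, temporal
    coefficient-of-variation masking with Otsu thresholding,
    fourth-order polynomial background surfaces, F/F0 normalisation),
    soma and correlated-activity ROI segmentation with retrograde-label
    (WGA) classification, dual-criterion responder calling with
    high-potassium exclusion and K+-normalised amplitudes,
    co-expression class accounting and responsive-area fractions,
    single-molecule FISH (RNAscope) dot counting with rolling-ball
    background subtraction and intensity-based cluster-to-dot
    correction, and the matching statistics layer (percentile-bootstrap
    ratio-of-means confidence intervals, Shapiro-Wilk gating,
    Kruskal-Wallis with Dunn post-hoc, one-way ANOVA with Holm-Sidak
    post-hoc, paired Wilcoxon). A synthetic-data module generates
    movies and slides with complete ground truth so every stage is
    testable without real recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
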