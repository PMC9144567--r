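Package: somnograph
Title: Attention-Guided Spatiotemporal Graph Networks for EEG Sleep Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Five-class sleep staging (W, N1, N2, N3, R) from multi-channel
    EEG using differential-entropy band features on an electrode graph, a
    spatiotemporal graph convolutional network with fused static and dynamic
    adjacency, multi-scale dilated temporal convolutions, and a joint
    frame-by-electrode attention block. Includes EDF/EDF+ reading and
    writing with hypnogram harmonization (R&K to AASM), a synthetic
    polysomnography simulator with Markov stage dynamics, subject-wise
    cross-validation, and the standard scoring metrics (accuracy,
    macro-precision/recall/F1, Cohen's kappa).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: signal, stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, MASS, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
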