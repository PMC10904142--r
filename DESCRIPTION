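Package: gcpnet
Title: Chirality-Aware SE(3)-Equivariant Graph Networks for 3D Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements geometry-complete graph neural networks for 3D
    molecular and particle graphs: per-edge local orthonormal frames, the
    geometry-complete perceptron (a learnable map on paired scalar and
    3-vector feature channels), geometry-complete graph convolution with
    equivariant node-position updates, and hand-written reverse-mode
    gradients so the networks can be trained without external deep-learning
    frameworks. Ships synthetic task generators (R/S chirality recognition
    on tetrahedral stereocenters; Newtonian many-body trajectory
    forecasting under electrostatic, gravity, and Lorentz-like fields),
    featurization for point clouds, training and evaluation loops, and
    property audits for SE(3) equivariance, geometric self-consistency,
    and frame completeness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
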