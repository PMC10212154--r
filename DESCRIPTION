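Package: mocapkit
Title: Marker-Based Motion Capture Reconstruction, Feature Learning and
    Transition Synthesis
Version: 0.1.0
Authors@R: person("Mocapkit", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for marker-based human motion capture pipelines:
    reading and writing hierarchical skeleton motion files (BVH and the
    CMU ASF/AMC dialect), forward kinematics and per-frame pose features
    (root-relative 96-dimensional point clouds, angular velocities, a
    five-part body partition), direct linear transformation (DLT) camera
    calibration, multi-camera triangulation with reconstruction
    uncertainty statistics and two-step iterative lens-distortion
    refinement, unsupervised frame embedding with a convolutional
    restricted Boltzmann machine trained by contrastive divergence,
    similar-frame detection, motion-graph construction with blended
    style-to-style transition synthesis, and agreement analysis of paired
    joint-angle waveforms via the coefficient of multiple correlation.
    Includes synthetic generators for skeletons, styled cyclic motions,
    camera rigs and two-system joint-angle recordings with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
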