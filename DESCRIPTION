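Package: stiffarm
Title: Endpoint Stiffness Synthesis and Muscle Synergy Analysis for a
    Planar Tendon-Driven Arm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a planar two-link, tendon-driven arm in which muscle
    activations set the endpoint stiffness of the hand. Provides the linear
    map from muscle activations to the vectorized endpoint stiffness matrix,
    exact characterization of the feasible activation set (generically a line
    segment in the activation hypercube) under static-equilibrium and
    desired-stiffness constraints, quadratic-program extremization of
    metabolic energy over that set, muscle-synergy constraint analysis
    including the two-synergy shoulder/elbow basis observed in human
    co-contraction experiments, and workspace-wide maps of realizable
    stiffness-ellipse orientations and achievable energy reduction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
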