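Package: eikloc
Title: Inverse Localization of Earliest Cardiac Activation Sites via the
    Viscous Eikonal Equation
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies the midpoints of earliest-activation sites (root
    points) in cardiac tissue from an activation-time map observed on part
    of the tissue boundary.  Electrical activation is modelled by the
    viscous Eikonal equation with an anisotropic squared-conduction-velocity
    tensor; the sites are recovered by minimizing the boundary misfit with a
    volume-expression shape derivative, an adjoint state, and an H1-smoothed
    perturbation field that iteratively relocates the source midpoints.
    Includes P1 finite-element assembly on structured triangular meshes, a
    Newton solver and a linear Hopf-Cole solver for the state equation,
    synthetic observation generation (subsampling, uniform noise,
    inverse-distance interpolation), and a fully self-contained 2D
    unit-square benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
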