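Package: activedrop
Title: Morphodynamics of Surface-Attached Active Nematic Drops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum simulation of a two-dimensional drop of active nematic
    fluid pinned to a rigid substrate. The nematic order is quasi-static
    (harmonic director field or stationary Landau-de Gennes Q-tensor with
    winding-number anchoring), and drives incompressible Stokes flow through an
    active stress; the free liquid-air interface moves with the fluid under
    capillary traction. The package provides the moving-boundary finite-element
    solver (Taylor-Hood elements on an unstructured triangulation that tracks
    the interface), diagnostics (vortex and defect censuses, mirror asymmetry,
    entropy production rates, morphology classification, scaling-law fits),
    and experiment drivers for state-diagram sweeps and time-dependent
    anchoring protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
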