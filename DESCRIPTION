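Package: porozero
Title: Large-Deformation Biphasic Poroelasticity with Vanishing Porosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-element framework for large-deformation biphasic
    (solid-fluid) poroelasticity based on mixture theory, reformulated so the
    governing equations remain solvable where the fluid volume fraction
    vanishes locally. Implements an axisymmetric mixed MINI/P1/P1
    discretization with a monolithic Newton solver and BDF time integration,
    a method-of-manufactured-solutions verification harness with symbolic
    source derivation, a locally squeezed porous-cylinder benchmark that
    drives complete local fluid expulsion, and a steady traveling-wave-frame
    solver for peristaltic cerebrospinal-fluid flow in the perivascular
    space of a penetrating arteriole, including volume-flow-rate and
    parameter-sweep analyses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
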