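Package: singtrap
Title: Matched Asymptotics for Diffusion in Singularly Perturbed Cellular Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers for diffusion in two- and three-dimensional bounded domains
    containing many small, well-separated interior compartments (synapses,
    protein clusters, biomolecular condensates, quorum-sensing cells).
    Implements Neumann Green's functions of the modified Helmholtz equation in
    the unit disk, rectangle, unit sphere and box, together with their
    zero-degradation pseudo-Green's counterparts; non-perturbative
    logarithmic-sum steady-state solutions in 2D and two-term epsilon
    expansions in 3D for three compartment boundary models (prescribed
    concentration, semi-permeable interface, well-mixed reaction network);
    Ostwald-ripening radius dynamics with extinction handling; accumulation
    times of diffusive relaxation via Laplace-space asymptotics; reduction of
    the quorum-sensing PDE-ODE model to a Green's-function-coupled ODE system
    (with a Sel'kov glycolytic example and a Kuramoto analogue); and
    steady-state volume transmission with a randomly switching boundary.
    A validation harness provides exact radial solutions, finite-difference
    and Monte Carlo oracles, trap-shape capacitances and a seeded
    configuration generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
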