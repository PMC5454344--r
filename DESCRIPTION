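Package: porocyl
Title: Steady-State Large-Deformation Poroelasticity of a Soft Annular Cylinder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvers for the steady radial deformation of a soft poroelastic
    cylinder (an artery-wall or tissue-annulus model) driven by radially
    outward fluid injection. Implements six model variants combining
    linearized or rigorous kinematics, linear or Hencky (logarithmic-strain)
    elasticity, and constant or Kozeny-Carman deformation-dependent
    permeability, under either a fixed (constrained) outer boundary or an
    applied radial effective stress, with flow driven by an imposed flow rate
    or an imposed pressure drop. Closed-form solutions are provided where the
    governing ODE is linear; the general case is solved by Chebyshev spectral
    collocation with damped Newton iteration on an unknown deformed domain.
    Continuation tools trace pressure-drop/flow-rate load curves, detect fold
    (limit) points including the maximum supportable pressure drop, and
    resolve the two coexisting solution branches. Post-processing computes
    pressure and velocity profiles, porosity and stress extrema, a macroscopic
    force balance, and solid-mass conservation checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
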