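Package: peroxff
Title: Pairwise-Additive Hydrogen Peroxide Force-Field Toolkit
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for a four-site pairwise-additive hydrogen peroxide
    (H2O2) model built on OPLS-style potential functions with a constrained
    Ryckaert-Bellemans dihedral. Provides the model geometry and energy
    terms, estimators for every bulk-liquid property derived from NPT time
    series (fluctuation thermodynamics, dielectric constant, Einstein
    diffusion, hydrogen-bond counts, cosine-flow shear viscosity, enthalpy
    of vaporization with a self-polarization correction), liquid-vapor slab
    analysis (density profiles, coexistence, vapor pressure, surface
    tension, boiling point, critical-point fits with fixed critical
    exponent), and the neural-network surrogate parametrization pipeline
    (normalization, small feed-forward regressors, weighted experimental
    target function, global random search and local refinement), together
    with seeded synthetic generators that invert each estimator for
    verification, GROMACS-dialect itp/gro/xvg text I/O, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
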