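Package: ligninpress
Title: Analysis of Glass Transition, Transport and Elasticity in Moist Amorphous Lignin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale analysis toolkit for molecular-dynamics observables of
    moist softwood lignin and for hot-pressed paper-sheet tensile data.
    Estimates the glass-transition temperature from dilatometry curves by
    bilinear, hyperbolic and onset methods, applies Williams-Landel-Ferry rate
    shifting, computes diffusivities from displacement time series via the
    Einstein relation with Arrhenius activation energies and per-molecule
    diffusivity distributions, extracts Young's modulus, Poisson's ratio and
    bulk modulus from uniaxial deformation records, and models the branched
    26-unit softwood lignin chain topology with moisture-dependent system
    compositions. A synthetic-data module generates every input with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    minpack.lm,
    zoo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
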