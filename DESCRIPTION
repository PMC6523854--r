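Package: cgmie
Title: Coarse-Grained Molecular Dynamics of Ionic-Liquid Cellulose Solutions with Mie Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained molecular dynamics simulator for mixtures of the
    ionic liquid 1-butyl-3-methylimidazolium chloride ([bmim][Cl]), cellulose
    and water. Pair interactions use the generalized Mie n-m potential with
    Lorentz-Berthelot mixing, electrostatics are evaluated by Ewald summation,
    and equations of motion are integrated under NVE, Nose-Hoover NVT and
    isotropic Nose-Hoover NPT with rigid SPC/E water handled by SHAKE/RATTLE.
    Builders construct the five-site ionic-liquid pair, the six-site-per-
    cellobiose cellulose chain, multi-chain fibers and solvated boxes; analysis
    routines compute equilibration points, equilibrium densities with
    uncertainties, mean absolute percentage deviations against reference data,
    and site-site radial distribution functions. Trajectories are written as
    extended-XYZ text with per-frame observables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
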