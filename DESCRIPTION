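Package: hydrocomplex
Title: Rigid-Body Hydrodynamics and Electrokinetics of Glycoprotein
    Complexes in Solution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterisation of antibody-receptor and other multi-lobed
    glycoprotein complexes from solution measurements and from structure.
    Implements a boundary-element Stokes solver (stick boundary conditions,
    single-layer formulation) for translational diffusion and intrinsic
    viscosity of rigid triangulated bodies, with 1/N triangle-count
    extrapolation and conformational-ensemble averaging; rolling-probe
    molecular surface triangulation with coalescent mesh decimation; DLS
    cumulant analysis of intensity autocorrelation traces; reduction of
    electrophoretic mobility to zeta potential and Debye-Hueckel-Henry
    effective charge; Henderson-Hasselbalch net-charge titration and
    isoelectric point; persistent residue-contact maps over structural
    ensembles; and seeded synthetic-data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
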