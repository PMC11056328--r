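Package: fontanflow
Title: Hemodynamic Quantification of Fontan Circulation from 4D-Flow CMR
    Velocity Fields
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for functional evaluation of the Fontan (total
    cavopulmonary connection) circulation from segmented 4D-flow cardiac
    magnetic resonance velocity fields. Provides plane-based blood flow
    quantification and derived circulation parameters (systemic-to-pulmonary
    collateral flow, effective cardiac index, pulmonary branch flow
    asymmetry), streamline tracing with an adaptive Runge-Kutta 4(5)
    integrator and caval flow distribution to the pulmonary arteries,
    voxel-level kinetic energy and viscous energy-loss fields with the EL/KE
    flow-efficiency index, sectional jet-shape metrics (wall shear stress,
    jet angle, flow eccentricity), analytic flow phantoms with attached
    ground truth for validation, and a cohort statistics layer
    (age-adjusted partial correlations with leverage-point exclusion, group
    comparisons, correlation z-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    rhdf5,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
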