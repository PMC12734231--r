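Package: lvmech
Title: Left-Ventricular Tissue and Flow Mechanics from Endocardial Surface Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of left-ventricular mechanics from time-resolved
    triangulated endocardial surface meshes, as used in exercise stress
    echocardiography studies. Computes divergence-theorem volume curves and
    diastolic filling indices (E/A ratio on dV/dt), surface Lagrangian strain
    by polar decomposition of per-triangle deformation gradients with global
    principal, secondary, longitudinal and circumferential strain time
    courses, dimensionless hemodynamic forces from a boundary integral of
    wall and orifice velocities with the six longitudinal-force parameters,
    mean intraventricular vorticity on gridded velocity fields, and vortex
    formation time from transmitral flow. A synthetic ventricle generator
    (prolate-spheroid geometry, E/A-structured filling waveforms, torsion and
    longitudinal/circumferential shortening, cohort sampling across exercise
    phases) provides ground-truth data, and a cohort statistics layer
    produces mean +/- SD summary tables, Welch t-tests and linear
    regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
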