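Package: pelviflow
Title: Virtual Pressure-Flow Studies of the Renal Pelvis and Ureter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico analogue of the Whitaker pressure-flow study for
    congenital hydronephrosis. Generates synthetic luminal geometries of the
    renal pelvis, ureteropelvic junction and proximal ureter (or reads
    segmented surfaces and voxel masks), builds tagged tetrahedral volume
    meshes, solves steady incompressible Stokes and Navier-Stokes flow with a
    mixed Taylor-Hood finite-element discretisation, sweeps physiological
    urine flow rates, and classifies obstruction severity by whether the
    pelvis-to-outlet pressure difference rises with flow. Includes closed-form
    Hagen-Poiseuille oracles and grid-convergence studies for solver
    verification.
License: MIT + file LICENSE + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
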