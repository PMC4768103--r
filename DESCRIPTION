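Package: vortexlcs
Title: Lagrangian Coherent Structure Analysis of Diastolic Vortex Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies diastolic vortex ring formation in the left ventricle
    from time-resolved three-dimensional, three-component (4D flow) velocity
    fields. Provides readers and writers for gridded velocity data, phase
    background correction and velocity-aliasing unwrapping, backward
    Runge-Kutta particle advection with finite-time Lyapunov exponent (FTLE)
    fields, automatic delineation of Lagrangian coherent structure (LCS)
    vortex boundaries, slice-summation volumetrics, vortex-wall interaction
    metrics (sphere-equivalent distance, effective diameters, vortex
    formation ratio), group statistics, and a synthetic-flow generator with
    analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse,
    withr
Config/testthat/edition: 3
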