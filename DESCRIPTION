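Package: liverreg
Title: Error Propagation from Surface Completion into Rigid and Non-Rigid
    Liver Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthetic-data pipeline for studying how errors in the
    completion of partially visible intra-operative liver surfaces
    propagate into rigid and non-rigid 3D-3D registration. Provides a
    two-lobed watertight liver phantom generator with interior fiducial
    markers and analytic wedge deformations, a partial-visibility
    simulator (posterior slicing, farthest-point downsampling,
    viewpoint-nearest selection), pluggable surface completion with a
    controllable distance-dependent error model, progressive-coverage
    patch extraction, multi-start iterative-closest-point rigid
    registration, coherent-point-drift non-rigid registration, and an
    evaluation layer computing per-vertex surface distance maps, target
    registration error (TRE), visible/invisible region stratification,
    TRE-versus-coverage curves and threshold sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
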