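Package: nirtomo
Title: Soft-Tissue Thickness Estimation from Near-Infrared Laser Backscatter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Synthetic end-to-end pipeline for estimating soft-tissue
    thickness over bone from the backscatter pattern of a scanned
    near-infrared laser grid. Provides a weight-tracking Monte-Carlo photon
    transport model for layered tissue, phantom and scan simulators,
    concentric-annulus optical feature extraction, two-ray laser
    triangulation with surface-normal estimation, marker-based rigid
    pre-alignment with trimmed iterative-closest-point refinement,
    Gaussian-process regression with an automatic-relevance-determination
    kernel evaluated by inverse repeated tenfold cross-validation, and
    fusion of surface geometry with predicted thickness into a 4D tomogram.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'camera.R'
    'cv.R'
    'features.R'
    'gp.R'
    'io.R'
    'montecarlo.R'
    'mri.R'
    'optics.R'
    'phantom.R'
    'profile.R'
    'registration.R'
    'render.R'
    'scan.R'
    'subject.R'
    'tomogram.R'
    'transform.R'
    'triangulation.R'
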