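Package: mlftrack
Title: Multi-Level Fiber Tractography for Branching White-Matter Pathways
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic fiber-orientation-distribution (FOD) peak tracking
    that iteratively spawns branch streamlines from FOD peaks left unused by
    earlier tracking levels, retaining only pathways that reach an anatomical
    target region. Includes a branching-bundle diffusion-MRI phantom generator
    with Rician noise, single-shell constrained spherical deconvolution with
    peak extraction, NIfTI/bval/bvec/TCK input and output, and evaluation
    metrics for topography preservation (TPI), streamline similarity (MADF),
    radial extent and endpoint density.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
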