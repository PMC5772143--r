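Package: lifetract
Title: Ensemble Tractography and Linear Fascicle Evaluation on Synthetic Diffusion Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and statistically validates short white-matter tracts on
    synthetic diffusion-MRI phantoms. Implements a multi-compartment stick/tensor
    phantom generator with Rician noise and two-session test-retest structure,
    diffusion tensor fitting, single-shell constrained spherical deconvolution
    with peak extraction, probabilistic streamline tractography with a
    multi-angular-threshold ensemble, linear fascicle evaluation (non-negative
    least-squares connectome optimisation and pruning), cross-validated
    virtual-lesion strength-of-evidence statistics, endpoint-ROI tract
    segmentation with outlier removal, endpoint density and ROI proximity
    analysis, and percentage-overlap probabilistic visitation atlases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
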