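Package: dwiQC
Title: Automated Motion-Artifact Quality Control for Pediatric Diffusion MRI
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Volume-level motion-artifact detection for diffusion-weighted MRI
    using a three-dimensional convolutional neural network, together with the
    surrounding workflow: NIfTI/FSL-gradient input and output, class-balanced
    curation, subject-level k-fold cross-validation, confusion-matrix metrics
    and decision-threshold calibration, a synthetic multi-shell diffusion
    phantom with parametric slice-dropout and interleave artifact simulation,
    weighted-least-squares diffusion tensor fitting with FA/MD/RD/AD maps, and
    a downstream quality-control impact analysis based on Lin's concordance
    correlation coefficient and per-subject t/F tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
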