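Package: csIQA
Title: Task-Specific Image Quality Assessment for Compressed-Sensing MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how full-reference
    objective image quality metrics relate to task-specific diagnostic
    confidence in accelerated brain MRI. Provides variable-density Cartesian
    k-space undersampling, l1-wavelet regularized compressed-sensing
    reconstruction, a five-metric full-reference image quality battery (RMSE,
    SSIM, FSIM, NQM, VIF), chance-corrected weighted inter-rater agreement
    (Gwet's AC2), constrained-logistic subjective-objective regression with
    Spearman rank correlation and residual-based metric ranking, and a
    synthetic phantom plus simulated-observer study generator so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
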