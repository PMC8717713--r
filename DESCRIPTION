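Package: petboot
Title: Image-Domain Bootstrap Resampling for Dynamic PET Studies
Version: 0.1.0
Authors@R:
    person("petboot", "developers", email = "petboot@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing uncertainty in kinetic parameters mapped
    from dynamic (4-D) positron emission tomography studies. A generalized
    linear model with a sub-ordinate Gaussian (copula-style) error process
    is fitted to the reconstructed image series: voxel and frame scale
    factors, a conditional quantile (Q) transform indexed by a local
    skewness surrogate, and a stationary spatial power spectrum estimated
    by periodogram averaging. Fitted models drive an image-domain
    bootstrap; a projection-domain multinomial bootstrap and an
    approximate coefficient-recycling bootstrap are provided for
    comparison. Non-parametric residue mapping converts voxel
    time-activity curves into maps of blood volume, distribution volume,
    flow, flux, mean transit time and extraction. Validation simulators
    (an attenuated 2-D parallel-beam Radon/Poisson/FBP scanner and a 1-D
    Fourier-multiplier Poisson deconvolution scanner with least-squares
    and EM-ML reconstruction) and a replication-based evaluation harness
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
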