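Package: locusdyn
Title: Simulation and Diffusion Analysis of Chromatin Locus Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for single-particle tracking of punctate nuclear loci in
    fluorescence movies, built around the telomere-tracking workflow used to
    study chromatin mobility: a seeded generator of subdiffusive (fractional
    Brownian), confined, and immobile locus trajectories with rendered movie
    stacks; Laplacian-of-Gaussian spot detection with subpixel refinement and
    optimal-assignment track linking; time-averaged mean squared displacement
    computation with anomalous-diffusion (4*D*t^alpha) fitting; and anchored
    Gaussian-mixture decomposition of per-trajectory apparent diffusion
    constants into fast, slow, and fixed populations, including perturbation
    presets for end-to-end pipeline runs and cross-condition comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
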