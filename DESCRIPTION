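Package: alffdev
Title: Developmental Analysis of Spontaneous Brain Activity via ALFF
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studies of the amplitude of
    low-frequency fluctuations (ALFF) in resting-state fMRI across development.
    Provides a seeded synthetic-cohort generator (4D volumes, rigid-body motion
    traces, tissue masks, phenotype tables), temporal preprocessing (volume
    discarding, Gaussian smoothing, detrending, Friston-24 plus white-matter and
    cerebrospinal-fluid nuisance regression, ideal band-pass filtering, motion
    quality control), voxelwise ALFF with global-mean standardization, a
    two-by-three diagnosis-by-age ANCOVA with Gaussian-random-field
    cluster-extent correction and Bonferroni post-hoc tests, quadratic
    age-trajectory modelling, and symptom prediction by linear support-vector
    regression with leave-one-out cross-validation and permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    car,
    withr,
    optparse
Config/testthat/edition: 3
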