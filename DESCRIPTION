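Package: interfield
Title: Montage Optimization for Interferential Epicranial and Transcranial
    Brain Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and electrode-montage optimization for
    interferential (temporal-interference) electric brain stimulation in a
    layered spherical head phantom. Builds five-tissue voxel phantoms, places
    10-20 disk electrodes on the scalp (transcranial, TES) or on the skull
    surface with an insulating back (epicranial, ECS), solves the quasi-static
    Laplace forward problem per electrode with a conservative finite-volume
    scheme, assembles lead-field matrices, and solves constrained convex
    programs that steer the interference envelope 2*min(||E1||,||E2||) toward
    deep targets under total-current (L1) and non-target field-power
    constraints. Includes the half-value-volume focality metric, a power-budget
    sweep with grand-optimal selection, an electrode-count reduction rule, and
    tidy pipelines comparing epicranial to transcranial montages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    tidyr,
    optparse
Config/testthat/edition: 3
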