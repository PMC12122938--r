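Package: feit
Title: Fuzzy Phase Classification Implemented in Electrical Impedance
    Tomography for Two-Phase Aeration Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-linear absolute conductivity reconstruction from
    multi-electrode boundary voltages (finite-element forward model, adjoint
    sensitivity Jacobian, Gauss-Newton iteration with Tikhonov regularization
    and L-curve selection), followed by two-cluster fuzzy c-means phase
    classification that maps each mesh element to a probabilistic air-bubble
    membership. Includes aeration time-series summaries (area-weighted mean
    membership, critical saturation time, overrun, min-max normalization) and
    a synthetic two-phase phantom and agitation-run simulator so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
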