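Package: minicircle
Title: Elastic Shapes and Hydrodynamic Transport of Supercoiled DNA Minicircles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models covalently closed DNA minicircles as inextensible Kirchhoff
    elastic rods with a prescribed linking-number deficit. Finds elastic-energy
    minimizing three-dimensional centerline shapes by Monte Carlo optimization of
    periodic cubic splines, computes writhe, twist and linking-number bookkeeping,
    classifies stability regimes (open circle, multistable, writhed-only), and
    predicts hydrodynamic observables: the hydrodynamic radius from slender-torus
    closed forms or rigid overlapping-bead models, and the diffusion and
    sedimentation coefficients, frictional ratio, and apparent partial specific
    volume measured in sedimentation-velocity analytical ultracentrifugation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    pracma,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
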