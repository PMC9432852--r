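Package: parasdm
Title: Host-Conditioned Species Distribution Modelling for Parasitic Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for ecological niche modelling of
    holoparasitic plants whose distribution is mediated by their host plants.
    Implements occurrence cleaning and per-cell spatial thinning, climate-model
    ensembling, correlation-matrix principal component reduction of collinear
    environmental rasters, a from-scratch L1-regularised maximum-entropy
    presence-background model with linear/quadratic/hinge features, spatially
    blocked (hierarchical checkerboard) cross-validation with AUC, omission
    rate and the Continuous Boyce Index, extrapolation diagnostics (ExDet
    NT1/NT2, most-influential covariate, percentage of data nearby), niche
    overlap statistics (Schoener's D, Warren's I), Jenks natural-breaks
    habitat classification with scenario change trends, and core-reserve
    delineation. A fully specified synthetic-world generator provides
    ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
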