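Package: zetaturn
Title: Zeta Diversity, Multi-Site Dissimilarity Models and Component
    Regressions for Plant Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing diversity and multi-site compositional
    turnover between components of a plant community (alien versus native,
    rare versus common) surveyed as subplot frequencies on a plot network.
    Implements zeta diversity of arbitrary order with random ("ALL") and
    nearest-neighbour ("NN") subsampling schemes and Simpson-equivalent
    normalization, power-law versus exponential decline-form comparison,
    multi-site generalized dissimilarity modelling by monotone I-spline
    regression with variation partitioning into spatial and environmental
    fractions, negative-binomial richness models with spatial residual
    checks, a resampling-based multivariate frequency test, incidence-based
    descriptors (Chao2, rarefaction, occupancy, extent of occurrence), and
    a synthetic metacommunity generator with controlled environmental
    sorting versus dispersal limitation for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    grDevices,
    jsonlite,
    pracma,
    splines,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
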