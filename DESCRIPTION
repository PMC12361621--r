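Package: hairbundle
Title: Unfolding and Single-Stereocilium Averaging of Two-Channel STED
    Images of Cochlear Hair Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated analysis of two-channel (actin + protein of
    interest) STED super-resolution images of cochlear hair-cell
    stereocilia bundles. Detects stereocilium centers inside a
    user-supplied row mask, orders them along the bundle, fits an
    arc-length parameterized spline, straightens ("unfolds") both
    channels along the spline, extracts maximum-normalized transverse
    profiles, rotation-aligns and averages single stereocilia using
    circumcircle-based local normals, subtracts background by one of
    three modes, and reads out protein peak positions as fractions of
    the inter-row space. Includes a seeded synthetic image generator
    that emulates inner and outer hair cell bundle geometries, labeling
    presets (rings, inter-row bands, intra-row bridges, granular
    puncta), a Gaussian point-spread function, and Poisson plus
    Gaussian camera noise, with exact ground truth for recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
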