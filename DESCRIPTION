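Package: greenwalk
Title: Eye-Level Street Greenness Exposure and Multilevel Walking Models on Synthetic Cities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess eye-level urban greenness exposure from
    street-level image tiles via the green view index (pooled vegetation-pixel
    fraction over four 90-degree views per street sampling point), and to relate
    that exposure to walking behaviour with multilevel models. Includes a fully
    synthetic, seed-reproducible city generator (street network, land-use
    parcels, amenities, street blocks, spatially autocorrelated vegetation
    field), a streetscape tile renderer with exact ground-truth vegetation
    masks, a rule-based shape-aware vegetation segmenter, buffer-based
    built-environment covariates (land-use entropy, intersection and population
    density, amenity counts, rail proximity), and from-scratch random-intercept
    regression: logistic via adaptive Gauss-Hermite quadrature and Gaussian via
    profiled maximum likelihood, with odds ratios, Wald intervals, intraclass
    correlations and simple-slopes post-hoc contrasts. Simulation modules
    generate walking decisions and walking times from published coefficient
    sets so that fixed effects, variance components and stratified effects can
    be recovered end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    lme4,
    png,
    igraph,
    withr
Config/testthat/edition: 3
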