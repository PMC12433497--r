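Package: layerdig
Title: Digestibility Coefficients and Feed Efficiency Phenotyping for Laying Hens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes apparent total-tract digestibility coefficients (dry
    matter, fat, uric-acid-corrected nitrogen, organic matter) from per-bird
    feeding-trial records and manure chemistry, together with feed-efficiency
    indicators (laying percentage, egg mass, feed conversion ratio, residual
    feed consumption). Includes a seeded mass-balance simulator of two-line
    feeding trials with known latent digestibilities, interquartile-range
    outlier screening, between-line Welch t-tests, significance-masked Pearson
    correlations, principal component summaries and linear prediction models,
    plus delimited-file input/output and a report renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    rlang
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
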