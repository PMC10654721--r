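Package: rotapest
Title: Temporal Crop Diversification and Pesticide Use Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify temporal crop diversification of cropping
    systems and relate it to pesticide use. Computes Hill-number (order 1)
    crop diversity indicators and their functional/taxonomic decomposition,
    scores pesticide reliance with the Treatment Frequency Index (TFI),
    tests the space-for-time substitution hypothesis with PERMANOVA under
    restricted permutations and multivariate dispersion diagnostics, and
    fits Tweedie (compound Poisson-Gamma) log-link regressions of crop-level
    TFI on crop identity and diversity indicators, with AIC model selection,
    type III Wald tests, marginalized means, FDR-adjusted contrasts and
    delta-method intervals. Includes a synthetic cropping-system network
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vegan,
    yaml
Suggests:
    glmmTMB,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
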