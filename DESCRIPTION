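Package: forestflux
Title: Multi-Dataset Forest Cover Change Detection and Cross-Product Agreement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparing forest cover change estimates
    across heterogeneous satellite-style products. Provides a
    LandTrendr-family temporal segmentation detector for annual spectral
    index (NBR-like) cubes, three alternative change-extraction recipes
    (stable-map categorical change, period-mean fractional tree cover
    change, annual loss accumulation), block-aligned scaling and a
    five-method resampling experiment, binary and sub-pixel fractional
    area accounting with provincial aggregation, pixel-level agreement
    maps and plain and weighted provincial Pearson correlations,
    sensitivity sweeps over detector parameters and forest definitions,
    and a synthetic scene generator with known ground truth so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
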