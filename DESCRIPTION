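Package: habitatrange
Title: Historical and Projected Habitat-Range Dynamics from Land Use and Biome Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates species' potential-natural and actual habitat-range
    sizes through time on regular latitude-longitude grids, by combining
    extent-of-occurrence coverage fractions, categorical biome maps, a
    habitat-to-biome crosswalk, and gridded cropland/pasture/urban land-use
    fractions with uncertainty variants. Provides fractional polygon
    rasterisation, fine-to-coarse area-conserving aggregation, delta-method
    climate bias correction, historical-to-future land-use harmonisation,
    range-change statistics (percentile fans, critical-loss shares, marginal
    loss against cumulative converted area, bootstrap resampling, multi-model
    aggregation), a scenario registry, and a synthetic-world generator with an
    exactly solvable fixture so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    ggplot2
Config/testthat/edition: 3
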