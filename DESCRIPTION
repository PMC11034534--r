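Package: desertmap
Title: Classify Census Tracts as Pharmacy Deserts from Block-Level Access
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies US census tracts as pharmacy deserts by combining a
    low-income indicator (poverty share or income relative to the nearest
    metropolitan area) with a low-access indicator computed by areal
    interpolation over census-block centroids and urbanicity-specific
    great-circle radii. Includes a synthetic-geography generator with
    ground-truth labels known by construction, group comparison tables
    (Welch t tests, chi-square tests, Benjamini-Hochberg correction),
    state and national roll-ups, and GeoJSON choropleth export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    purrr,
    jsonlite,
    yaml,
    geosphere,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
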