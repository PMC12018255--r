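Package: bananaclim
Title: Climatic, Edaphic and Socio-Economic Suitability Analysis for
    Export Banana Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for area-weighted rectilinear (R90) bioclimatic envelope
    estimation from gridded crop-distribution data, irrigation-stratified
    suitability classification under current and future climates,
    cardinal-value beta-function relative-yield modelling, and the
    post-processing and validation arithmetic of classified plantation maps
    (minimum-patch contiguity filtering, confusion-matrix metrics). Includes
    a seeded synthetic-scenario generator so the full pipeline runs without
    external geodata, a plain-text raster dialect for reproducible I/O, and
    tidy summaries with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
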