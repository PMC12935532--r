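Package: carbofoot
Title: Commodity-Driven Deforestation Attribution and Committed Carbon
    Emission Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale land-use change bookkeeping pipeline that attributes
    tree-cover loss to agricultural and forestry commodities and accounts for
    the committed carbon emissions of the resulting deforestation. Forest-loss
    pixels on an aligned raster stack are classified by a sequential
    attribution hierarchy (commodity maps, land-use maps, land-use mosaics,
    dominant-driver fallback, with fire exclusion); spatially unresolved loss
    is allocated to land uses and commodities through a two-step statistical
    land balance on agricultural statistics; committed emissions are computed
    from above- and below-ground biomass, deadwood, litter and soil organic
    carbon with a deduction for the replacing commodity's plant carbon stock;
    peatland drainage emissions accumulate annually via land-use by biome
    emission factors; and every country-commodity estimate carries an
    integrated quality index. A synthetic-landscape generator with embedded
    ground truth makes the whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
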