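Package: paleocarb
Title: Millennial-Scale Reconstruction of Northern Terrestrial Carbon Stocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gridded bookkeeping reconstruction of terrestrial carbon stocks
    north of 23 degrees latitude from the Last Glacial Maximum (21 ka) to
    preindustrial, at millennial time steps. Provides a seeded synthetic-world
    generator (two pseudo climate-model ensembles, ice-sheet and shoreline
    chronologies, loess regions, peat growth curves, pollen-style training
    samples), a vote-fraction biome classifier, a logistic permafrost-extent
    model driven by mean annual air temperature, a multi-pool carbon ledger
    (mineral soil, exposed and inundated shelf, peat, deep loess, subglacial,
    post-glacial accrual), coefficient-of-variation uncertainty propagation,
    and translation of net land-carbon transfers into atmospheric CO2 (ppm).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
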