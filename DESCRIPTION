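Package: conecap
Title: Energy-Budget Carrying Capacity from Conifer Cone Feeding Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating red squirrel (Sciurus vulgaris) carrying
    capacity in conifer plantations from ground feeding surveys. Converts
    transect cone counts and cone-length measurements into per-square-metre
    energy densities via a scale-length regression (Sitka spruce) and a
    length-based seed allometry (lodgepole pine), extrapolates energy over
    mature and squirrel-occupied stand areas, and derives energy-based
    carrying-capacity and actual-population intervals alongside an area-based
    density estimate. Includes a stand-ledger habitat accounting module with a
    composition-correction formula for nurse-crop stands, cross-year change
    statistics (fold changes, capacity decline ranges, rank-sum density
    comparisons), and a synthetic survey generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
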