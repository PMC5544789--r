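Package: forestca
Title: Weights-of-Evidence Cellular-Automata Simulation of Amazonian
    Deforestation and Carbon Emissions under Forest-Code Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates regionalized land-cover transition models
    (weights-of-evidence spatial susceptibility plus per-region annual
    transition rates) from two dated categorical rasters, and projects
    deforestation, secondary-vegetation dynamics and committed carbon
    emissions forward with a stochastic patch-based cellular automaton
    (patcher/expander allocation, road-network feedback). Includes riparian
    permanent-preservation-area (APP) buffer construction under the 1965 and
    2012 Brazilian Forest Codes, deforestation-leakage transfer between
    regions, carbon stock/emission bookkeeping, fuzzy map-similarity
    validation, and a synthetic-landscape generator with known true rates so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
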