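Package: phenostab
Title: Seasonal Structure and Multidimensional Stability of Mutualistic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how the within-year (seasonal) organization of
    mutualistic interactions affects the stability of bipartite
    plant-pollinator networks. Builds month-resolved interaction tables
    (synthetic or from long-format records), derives phenological overlap
    indices among and within guilds, integrates an obligate-mutualism
    community model with saturating functional response and competition for
    mutualistic partners to its ecological equilibrium, and quantifies four
    facets of stability: feasibility, persistence, resilience and
    robustness. Includes a factorial simulation grid over mutualism and
    competition strengths with paired with/without-seasonality contrasts, a
    phenology randomization null model, equilibrium network indices, and a
    mixed-model path analysis attributing stability effects to diversity,
    connectance, interaction overlap and total abundance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
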