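Package: landsim
Title: Daily Grid-Based Simulation of Crops, Soil Water and Coupled C-N-P
    Cycling in Agricultural Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A daily time-step, grid-based simulator of arable and grassland
    agro-ecosystems.  Each grid cell carries a three-layer capacity
    ("tipping-bucket") soil water model with HYPRES pedotransfer retention
    curves, RothC-style soil organic carbon turnover extended with coupled
    nitrogen and phosphorus stoichiometry, mineral N dynamics (nitrification
    and denitrification with N2O and N2 emission kernels, leaching, runoff),
    a two-pool mineral P model with daily re-equilibration, dynamic bulk
    density, and a light-use-efficiency crop/grassland growth model with
    water and nutrient stress.  Runoff and dissolved nutrients are routed
    laterally between cells towards ditches so that catchment discharge and
    nutrient loads can be aggregated.  A non-dominated-sorting differential
    evolution optimiser maps Pareto trade-offs between yield, nitrate
    leaching and N2O emissions under alternative fertiliser management.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
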