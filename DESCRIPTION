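Package: standclim
Title: Climate-Sensitive Cohort Stand Dynamics and Forest Carbon Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cohort-based, climate-sensitive growth-and-yield simulation for
    forest inventory plot networks. Estimates empirical disturbance regimes
    (per-class decadal probabilities and basal-area-killed magnitude
    distributions) from repeat inventory measurements, simulates 100-year
    stand dynamics with three climate-driven mortality pathways (species
    viability envelopes, viability-modified maximum stand density index, and
    an elevation-window climate-change rule applied to cohort establishment
    climates), accounts for aboveground carbon in live trees and snags, and
    runs factorial climate x mortality x disturbance sensitivity experiments
    with common random numbers. Includes a synthetic-data generator that
    emulates inventory plot networks along elevation and climate gradients so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
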