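Package: displaceabm
Title: Agent-Based Simulation of Conflict-Induced Forced Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hierarchical agent-based simulator of population displacement
    triggered by armed conflict. Synthetic person and household agents perceive
    georeferenced conflict events through a Theory-of-Planned-Behavior decision
    model with spatial and temporal decay, memory retention, a logistic
    migration-intent function, intra-household probability averaging and an
    inter-household peer-threshold rule. Includes a scaled synthetic-population
    generator, ACLED-style conflict-event ingestion and scenario sampling,
    coordinate-descent calibration against an observed daily border-crossing
    series, and reporting utilities for daily, demographic and administrative
    disaggregation of displacement flows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
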