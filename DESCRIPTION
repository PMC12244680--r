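Package: aridfarm
Title: Agent-Based Simulation of Runoff-Fed Agriculture in Arid Watersheds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily water-balance simulation of runoff-harvesting agriculture in
    small arid watersheds, coupled to annual water-limited crop yields,
    wheat-equivalent labor economics, and loss-averse farm decision rules.
    Implements SCS Curve-Number runoff on a gridded terrain with D8 routing,
    terrace water columns with evaporation and infiltration, grapevine and
    wheat yield response functions, and replicated Monte-Carlo climate-stress
    experiments (runoff-ratio sweeps, consecutive-drought impact, post-drought
    recovery time, and wetter-climate scenarios), together with synthetic
    watershed and synthetic desert-climate generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
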