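Package: spatpunish
Title: Direct and Indirect Punishment in the Spatial Prisoner's Dilemma
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulator for a two-stage prisoner's dilemma on a
    periodic square lattice with Moore neighborhoods. Players combine a
    cooperation choice with a costly-punishment choice (strategies CN, DN,
    CP, DP); punishers pay a per-act cost to fine defecting neighbors,
    either among their eight direct neighbors (direct punishment) or among
    their sixteen second-order neighbors at Chebyshev distance two
    (spatially indirect punishment). Strategies evolve by asynchronous
    pairwise Fermi imitation. Includes ensemble drivers for cost/fine
    sweeps, cooperation phase maps, threshold extraction, block-invasion
    replays, and punishment-event statistics, with plain-text snapshot,
    CSV and YAML/JSON configuration interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
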