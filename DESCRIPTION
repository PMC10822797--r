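Package: larvadisp
Title: Optimal Vertical Swimming and Cross-Shore Larval Dispersal in
    Upwelling Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the cross-shore dispersal of coastal marine
    invertebrate larvae in a two-layer upwelling circulation with discrete
    vertical swimming and a simple energy budget.  Provides the classical
    vertical-migration behavioral archetypes (passive drifting, ontogenetic
    and diel vertical migration, and a hybrid), a Trajectory Score that
    weighs predator avoidance, starvation avoidance, nearshore settling and
    terminal energy for metamorphosis, and a backward-induction dynamic
    programming solver that constructs state-dependent optimal swimming
    policies.  Includes Monte-Carlo experiment drivers (parameter sweeps,
    feeding thresholds, subscore comparisons) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
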