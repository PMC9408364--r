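Package: wsbsim
Title: Agent-Based Simulation of Safety-Behavior Adoption on Construction Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A seeded, replicable agent-based simulator of how group-level
    context -- intra-group informal interaction (IGII), group knowledge
    sharing (GKS), and group identification (GI) -- cultivates construction
    workers' willingness to adopt safety behaviors. Workers walk randomly on
    a toroidal lattice of context patches, accumulate willingness from the
    patches they visit, and exhibit safety behavior stochastically once net
    willingness turns positive. The package provides configuration
    validation, the per-tick dynamics, onset and plateau metrics, replicated
    scenario suites for single- and multi-factor experiments, a calibration
    routine for the cultivation gain, and a command-line interface with CSV
    and plot outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
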