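Package: cellswarm
Title: Social Learning Dynamics of Interacting Agent Populations on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models populations of adaptive agents (for example interacting cells)
    that repeatedly play two-action games against neighbours drawn from a weighted
    interaction network. Provides a stochastic round-based simulator in which every
    agent learns by policy hill-climbing, a constrained linear differential-equation
    model of the expected learning dynamics with sliding on the boundary of the
    strategy cube, and an eigenvalue-based classifier that certifies the joint
    strategy dynamics as convergent, non-convergent on a cyclic set, or
    indeterminate, including closed-form parity rules for ring topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'games.R'
    'io.R'
    'phc.R'
    'dynamics.R'
    'analysis.R'
    'compare.R'
    'show-methods.R'
    'cellswarm-package.R'
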