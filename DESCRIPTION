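Package: fatedyn
Title: Cell-Fate Dynamics as Deterministic, Nonautonomous and Random Dynamical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Executable dynamical-systems infrastructure for modelling cell-fate
    determination. Provides autonomous, nonautonomous (process and skew-product)
    and random dynamical systems with their defining axioms (identity, semigroup,
    causality, cocycle) as seeded numerical checks; Bernoulli schemes and shift
    spaces as driving noise models with cylinder-set measures; numerical
    estimation of global, forward, pullback and random pullback attractors via
    the directed Hausdorff distance, plus long-transient diagnostics;
    Kauffman-style random Boolean networks with exhaustive cycle, basin and
    perturbation-return analysis; and the gene-regulatory-network chain from
    mass-action reaction kinetics through stochastic differential equation
    ensembles to quasi-potential landscapes, valley identification and
    fate-transition detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
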