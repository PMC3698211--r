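Package: bistacert
Title: Certification of Bistability in Mass-Action Reaction Networks
Version: 0.1.0
Authors@R: person("bistacert", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse and certify bistability in biochemical
    reaction networks with mass-action kinetics. The package finds and
    classifies equilibria by seeded multistart Newton iteration, certifies
    axis-aligned boxes as subsets of the domain of attraction of a stable
    equilibrium by solving linear-matrix-inequality feasibility problems
    for quadratic systems, computes time-resolved normalized parametric
    sensitivities via the forward sensitivity equations, maps fold and cusp
    bifurcations by pseudo-arclength continuation, and certifies the
    persistence of bistability under multi-parameter uncertainty through
    steady-state exclusion certificates built on linear relaxations of the
    steady-state equations. A nine-species model of the yeast galactose
    (GAL) regulatory switch is packaged as the flagship example, together
    with small closed-form fixtures used as test oracles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
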