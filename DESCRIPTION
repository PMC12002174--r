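Package: lvgames
Title: Lotka-Volterra Dynamics, Game Classification, and Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying interacting populations where fitness
    differences arise both from pairwise interactions (the "game") and from
    unequal intrinsic growth rates. Implements generalized Lotka-Volterra
    abundance dynamics, replicator frequency dynamics, the coupled
    frequency/total-abundance system that links them, and a numerical test of
    when the two frameworks are dynamically equivalent. Provides the analytic
    classification of two-type dynamical outcomes (dominance, coexistence,
    bistability, extinction) as a function of the interaction matrix and the
    intrinsic growth rates, the growth-rate-shifted region boundaries, the
    critical growth-rate advantage that turns dominance into coexistence,
    fixed-point enumeration with linear stability, invasion fitness, and
    stepwise community assembly including cyclic (Rock-Paper-Scissors)
    communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
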