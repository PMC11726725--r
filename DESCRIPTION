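Package: ribostat
Title: Concentration Control of RNA Species by Inhibitor/Anti-Inhibitor Pairing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a primitive homeostasis mechanism in which short RNA
    inhibitors sequester an active RNA species (an agent such as a replicase)
    and complementary anti-inhibitors neutralise the inhibitors, all by
    reversible mass-action binding.  Provides closed-form and root-finding
    equilibrium analysis of the binding network, the system capacity (the
    reciprocal sensitivity of the equilibrium free-agent concentration to the
    total agent concentration), inverse design of inhibitor/anti-inhibitor
    totals for a target set point, deterministic forward-Euler simulation of
    perturbation and self-replication scenarios with Lyapunov convergence
    diagnostics, and a stochastic spatial multi-agent simulation of
    replicase-parasite-inhibitor populations.
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
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
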