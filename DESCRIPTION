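Package: evobinder
Title: Evolutionary Optimization Engine for Protein Binder Affinity Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in silico directed-evolution engine for maturing the affinity of a
    protein binder (an antibody fragment, nanobody or designed miniprotein) toward a
    fixed target. Starting from a binder/target complex, the engine repeatedly selects
    mutation sites and replacement residues under configurable policies, applies the
    mutations to a coarse-grained structural model, samples a conformational ensemble
    around the bound pose, scores every frame with one or more interface scoring
    functions, and prunes unproductive mutation lineages with consensus, Metropolis
    Monte Carlo or top-N criteria. Lineages accumulate across epochs into a directed
    acyclic graph whose width can be left free or held constant. Built-in coarse
    scorers (contact potential, screened electrostatics, contact count) and a
    synthetic-complex generator make the full protocol runnable at desk scale;
    adapter contracts let external mutators, samplers and scorers plug in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    yaml,
    jsonlite,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
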