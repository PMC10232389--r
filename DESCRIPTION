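Package: patchweb
Title: Patch-Dynamic Metacommunity Models of Food Webs Under Habitat Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-occupancy (Levins-type) metacommunity models for complex
    food webs in which basal species compete for patches through a
    competition-colonization tradeoff and consumers persist through
    bottom-up control. Provides generators for layered acyclic food-web
    topologies with the structural character of small island webs;
    hierarchical, weakened and intransitive competitive tournaments;
    numerical steady-state integration and analytic Lotka-Volterra-form
    equilibria of the occupancy dynamics; food-web complexity metrics
    (food chain length, omnivory, connectance) and basal diversity
    indices; and a patch-loss sweep driver that quantifies the
    non-monotone, oscillating response of diversity and food-web
    complexity to habitat destruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
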