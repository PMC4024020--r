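Package: netctrl
Title: Structural Controllability Analysis of Compartmentalized Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed metabolite networks from compartmentalized
    reaction lists and analyses their structural controllability: maximum
    bipartite matchings (Hopcroft-Karp), minimum driver-metabolite sets,
    driver-frequency sampling and classification (critical / high- /
    low-frequency), exact node control classes and the control mode of a
    network versus its transpose, link robustness classes (critical /
    ordinary / redundant) by Regin's orientation algorithm, modularity
    optimisation by simulated annealing with Guimera-Amaral role cartography
    (within-module degree, participation coefficient, roles R1-R7),
    degree/betweenness/closeness centrality profiles with tertile binning,
    and chi-square enrichment tests. Includes a synthetic reaction-set and
    planted-partition generator so the whole pipeline is testable without
    any particular genome-scale model.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
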