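Package: netgrid
Title: Grid Layouts for Biochemical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Compact, module-separated 2D grid layouts for biochemical
    networks. Interaction weights are derived from unweighted graph
    distances through configurable layout styles (common, compact,
    stretched) with optional intra-module weight boosts, and node
    placements on an integer grid are optimized by a neighborhood-test
    local search combined with re-optimization-after-perturbation
    restarts under a Manhattan-distance cost function. Includes bipartite
    construction from reaction tables, currency-metabolite filtering, a
    planted-partition generator of modular test networks, SVG rendering,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
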