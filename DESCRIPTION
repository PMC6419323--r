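Package: jointpart
Title: Partitioned Constrained Optimization for Articulated Joint Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models articulated 3D joint systems as constrained nonlinear
    programs (distance, pivot-angle, flexibility and cone constraints),
    partitions large joint graphs into independent sub-problems via
    community detection (greedy modularity, DBSCAN, k-means) with pinned
    virtual joints and cone constraints at the cuts, solves each
    sub-problem with a derivative-free linear-approximation trust-region
    optimizer, and quantifies the partitioning error against the
    non-partitioned solution. Includes a seeded synthetic problem
    generator with planted community structure, benchmark and
    runtime-scaling utilities, a JSON scene format, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
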