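Package: dyncomm
Title: Dynamic Communities in Proteins from Elastic Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects dynamic communities in protein structures with the
    Gaussian network model (GNM) and compares them against communities
    derived from molecular dynamics trajectories. Builds the contact
    Kirchhoff matrix from C-alpha or heavy-atom coordinates, computes
    mode-subset cross-correlation matrices, clusters the distance-
    transformed correlations with WPGMA linkage, and quantifies the
    agreement of partitions with Cohen's kappa, weighted closeness
    centrality correlation and the root-mean-square inner product of
    principal eigenvector sets. Includes an all-atom GNM screen that
    ranks mutant structures by how strongly they reshape the wild-type
    community architecture, and a synthetic bead-protein generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
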