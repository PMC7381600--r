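Package: myomatrix
Title: Sarcomere Branching and Myofibrillar Matrix Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the branching, connected network formed by
    sarcomeres in striated muscle ("the myofibrillar matrix") from labeled 3D
    electron-microscopy volumes. Provides a stochastic generator of
    ground-truth branching networks rendered as labeled volumes, overlap-based
    reconstruction of the sarcomere graph with classification of branch events
    (splits, merges, myofilament transfers and trades), myofibril tracking
    with a membrane-distance continuation rule and field-of-view filtering,
    per-volume branch-frequency and percent-branched summary statistics,
    whole-cell connectivity and minimal lateral path analysis, and group
    comparison by one-way ANOVA with Tukey HSD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
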