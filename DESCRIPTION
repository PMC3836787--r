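Package: ringnet
Title: Correlation-Threshold Gene Networks with Concentric Degree Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene co-expression networks by thresholding Pearson
    correlations of expression profiles, characterizes nodes by concentric
    (ring-wise) node degrees, classifies them into hubs, VIPs and high-hubs,
    ranks them by betweenness centrality, assesses scale-free degree
    distributions by discrete power-law maximum likelihood with a
    Kolmogorov-Smirnov bootstrap, and computes 2D/3D force-directed layouts
    by molecular-dynamics relaxation with a Runge-Kutta integrator.
    Includes synthetic generators for expression matrices with planted
    correlation modules and benchmark graphs with planted node roles, plus a
    command-line interface chaining the full workflow.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    tibble,
    dplyr,
    ggplot2,
    generics,
    withr,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
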