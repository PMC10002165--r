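Package: iegnet
Title: Immediate-Early-Gene Expression Connectomes in the Rodent Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares gene-expression-based functional
    connectivity networks from regional immediate-early-gene (e.g.
    Homer1a) densitometry tables. Starting from long-format relative-dpm
    measurements per animal, region of interest (ROI) and tissue section,
    the package averages section replicates, normalizes each animal
    against a reference white-matter region, computes group-wise Pearson
    correlation matrices with exact t-based p-values, thresholds them
    into weighted undirected brain networks, summarizes the networks with
    graph metrics (density, characteristic path length, clustering
    coefficient, connected components, degree and betweenness
    centrality), and tests group differences in edge weights, global
    strength and node centralities with exhaustive or Monte-Carlo
    permutation tests. A synthetic-data generator with configurable
    inter-ROI correlation structure supports calibration and power
    studies when raw data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
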