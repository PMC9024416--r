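Package: pelagos
Title: Diversity, Connectivity, and Assembly Processes of Pelagic Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the structure of depth-stratified pelagic
    microbial communities from OTU count tables: rarefaction and richness
    testing, compositional beta diversity (count-zero-multiplicative zero
    replacement, centred log-ratio transform, Aitchison distances,
    hierarchical clustering gated by similarity-profile permutation tests),
    sample proportionality networks with modularity and clustering
    coefficients, shared-OTU connectivity along horizontal and vertical
    gradients, null-model partitioning of community assembly into selection,
    dispersal, and drift (beta-mean-nearest-taxon distance, beta-nearest-taxon
    index, Raup-Crick), distance-based redundancy analysis with forward
    selection of environmental factors, and a synthetic multi-site,
    multi-depth community generator with known assembly regimes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
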