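Package: isletscape
Title: Islet and Extra-Islet Spatial Analysis of Multiplexed Pancreas Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing multiplexed imaging of pancreas tissue in
    type 1 diabetes: per-donor marker normalisation, unsupervised cell typing
    with signature-based annotation, percentile-threshold marker gating, islet
    instance detection from k-nearest-neighbour window composition, diffusion
    pseudotime staging of insulitis, CD8 T cell sub-state discovery in inflamed
    islets, cellular-neighbourhood identification with instance adjacency
    statistics, and hierarchical linear models of lobular patterning (intraclass
    correlation, two- and three-level mixed models with Satterthwaite inference).
    Includes a ground-truthed synthetic tissue generator so every stage is
    testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    igraph,
    lme4,
    deldir,
    jsonlite,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
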