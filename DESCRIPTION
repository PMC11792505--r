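Package: assemproc
Title: Attribution of Microbial Community Assembly Processes to Taxa and Sampling Units
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the two-step null-model framework for classifying pairwise
    community assembly processes in microbial communities (heterogeneous and
    homogeneous selection via the standardized effect size of the abundance-weighted
    beta mean nearest taxon distance; dispersal limitation, homogenizing dispersal
    and drift via the Raup-Crick metric on Bray-Curtis dissimilarity), and extends
    it with attribution analyses: a taxon-removal algorithm that quantifies the
    contribution of individual taxa or taxonomic groups (DTUs) to each process
    under shared randomizations, and a pair-counting analysis that quantifies the
    contribution of individual sampling units or groups (DSUs). Includes a Mantel
    correlogram gate for phylogenetic signal and a synthetic-community simulator
    with known assembly regimes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
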