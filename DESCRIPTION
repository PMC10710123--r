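Package: phyloprior
Title: Spatial Conservation Prioritization from Multi-Tree Phylogenetic Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Grid-based spatial prioritization of conservation areas from
    phylogenetic diversity computed over a collection of independent
    phylogenies plus species occurrence records. Computes per-cell average
    taxonomic distinctness (AvTD) and Faith phylogenetic diversity (PD),
    selects the index least coupled to species richness by Bayesian simple
    linear regression, classifies cells into rank quintiles, quantifies the
    robustness of the classification by jackknifing phylogenies, maps
    sampling ignorance, clusters cells by phylogenetic beta diversity
    (PhyloSor) with silhouette analysis, and accounts the contribution of
    endemic species and of protected-area polygons to total diversity.
    Includes a synthetic-data generator that emulates the statistical
    structure such analyses assume, so the whole pipeline runs end-to-end
    without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
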