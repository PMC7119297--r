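Package: scnrank
Title: Spectral Clustering Network Rank for Drug-Target Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates tumor, normal and cell-line expression profiles,
    a protein-protein interaction (PPI) skeleton and CRISPR-Cas9
    gene-essentiality screens into a pair of weighted networks that share
    the same PPI-derived skeleton.  The tissue network (node weights = log2
    fold change tumor vs normal, edge weights = Pearson correlation over
    tumor samples) is partitioned by a fold-change-weighted variant of
    normalized spectral clustering, with the number of clusters chosen by
    Hartigan's rule.  Clusters are aligned onto the cell-line network
    (node weights = CRISPR gene essentiality, edge weights = correlation
    over cell-line samples) and drug targets are ranked by a Target
    Influence score: the essentiality-weighted sum of maximum-magnitude
    products of correlations along the most-correlated path from the
    target to every cluster member, found by a Dijkstra search on
    -log|r| edge costs.  Ships a fully parameterized synthetic-data
    generator with planted cluster and hub-target ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
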