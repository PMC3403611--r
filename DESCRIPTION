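Package: katznet
Title: Seeded Katz Propagation for Disease-Gene Prioritization on
    Weighted Interactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by seeded Katz-centrality
    propagation on a weighted protein-protein interaction network, with
    locus-based calibration of the propagation strength via leave-out
    r-ratios.  Builds the disease-specific subnetwork from top-ranked
    genes, characterizes its topology by k-core decomposition and a
    core-periphery partition, and tests annotation terms, reference gene
    sets and tissue-abundance composition by hypergeometric enrichment.
    Includes a two-platform differential-expression screen (probe
    averaging, fold filter, rank transform, Wilcoxon rank-sum test,
    Benjamini-Hochberg FDR) that turns expression matrices into
    provenance-tagged seed genes, and a synthetic-data generator with a
    planted disease module so the whole pipeline can be exercised with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
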