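Package: magecol
Title: Genome-Resolved Ecology of Nitrifying Bacteria from Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-resolved microbial ecology built
    around Nitrospira surveys: species-level genome dereplication by detecting
    the discontinuity in pairwise average nucleotide identity (ANI),
    quantification of species abundance and richness by recruiting metagenomic
    reads to a database of 15 universal single-copy marker genes, pangenome
    construction by Markov clustering of a protein-similarity graph with
    threshold-based gene-cluster classification, compositional data analysis
    (multiplicative zero replacement, centred log-ratio transform, PCA,
    proportionality rho with permutation FDR), and Mantel permutation tests of
    phylogenetic signal in habitat preference and of geographic distance decay.
    Includes simulators for every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vegan,
    withr
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
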