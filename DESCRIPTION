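Package: phyloUnmix
Title: Tumor Subclone Deconvolution via Minimum Conflict-Free Row Splits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes multi-sample tumor variant presence/absence matrices
    into a minimum set of subclone rows forming a perfect phylogeny. Variant
    allele frequency (VAF) tables are thresholded into binary matrices, a
    containment digraph is built over distinct column supports, and the
    minimum conflict-free row split is obtained by solving the Minimum
    Uncovering Branching problem exactly with an integer-programming
    formulation and a specialized branch-and-bound solver. Includes the
    perfect phylogeny construction with VAF-annotated edge labels, a clonal
    tree simulator with Poisson/Binomial read-count noise, and an
    ancestor-descendant pair benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, Rcpp, jsonlite, ape
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Software, Phylogenetics, SomaticMutation, Genetics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'digraph.R'
    'io.R'
    'simulate.R'
    'mub.R'
    'split.R'
    'phylogeny.R'
    'evaluate.R'
    'pipeline.R'
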