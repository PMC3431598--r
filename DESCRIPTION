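Package: chemoreceptR
Title: Annotation and Evolutionary Analysis of Insect Chemosensory
    Receptor Gene Families
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Homology-based discovery of odorant (Or), gustatory (Gr) and
    ionotropic (Ir) receptor genes in draft genome assemblies, together with
    the downstream analyses such repertoires call for: classification of
    predicted models into intact genes, pseudogenes and assembly-truncated
    fragments; detection of tandem gene clusters; bootstrap-aware
    duplication-loss reconciliation of gene trees against a species tree;
    maximum-likelihood birth-death modelling of family-size evolution with
    ancestral copy-number estimates; and antennal expression analysis (FPKM,
    median expression calls, sex-enrichment, cross-species orthogroup
    concordance). Ships simulators for genomes with planted receptor genes,
    gene-family histories and count matrices so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
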