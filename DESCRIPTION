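Package: indolepath
Title: Genome-Based Prediction of Microbial Tryptophan Indole Derivatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts which indole derivatives of tryptophan a bacterial
    strain can produce from its proteome. Detects homologs of the pathway
    enzymes (aromatic amino acid aminotransferase, indolelactate
    dehydrogenase, amidase and others) with an affine-gap Smith-Waterman
    search under identity, coverage and E-value thresholds, applies a
    pathway-completeness rule on the tryptophan metabolic network,
    summarizes predictions at the species level, scores genotype-phenotype
    concordance against metabolite concentration tables, and tests
    gene-count/metabolite associations with Spearman correlation under
    Benjamini-Hochberg false discovery rate control. Includes a
    neighbor-joining clustering of enzyme homologs and a seeded synthetic
    data generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
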