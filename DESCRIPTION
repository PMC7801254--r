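Package: gutcatalog
Title: Species-Level Genome Catalogs from Large Microbial Genome Collections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds species-level genome and protein catalogs from large
    collections of microbial isolate genomes and metagenome-assembled
    genomes (MAGs). Implements quality scoring and filtering of assemblies,
    MinHash sketching with Mash-style distances, fragment-based ANI and
    alignment-fraction estimation, iteratively chunked species clustering
    at the 95% ANI boundary with score-based representative selection,
    conspecific dereplication, pan-genome core/accessory analysis from
    greedy protein clustering, construction of intraspecies single
    nucleotide variant (SNV) catalogs against species representatives, and
    diversity reporting (geographic Shannon diversity, rarefaction,
    phylogenetic diversity). Ships a synthetic genome collection generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
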