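Package: magcatkit
Title: Building and Analyzing Dereplicated Gut Microbial Genome Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing metagenome-assembled genome (MAG)
    catalogs and for the downstream analyses such catalogs support:
    MinHash (Mash-style) genome sketching and distances, two-step iterative
    species dereplication by average nucleotide identity with
    intactness-score representative selection, genome quality scoring and
    tiering, non-redundant genome counting, intra-species single-nucleotide
    variant density with chunked normality screening, human-epitope
    cross-reactivity scoring with taxon-disease association statistics, and
    abundance-stratified comparison of taxonomic profiles across sequencing
    depths. A synthetic-data generator plants ground truth (conspecific
    genomes at controlled identity, MAG-style degradation, substitutions,
    epitope occurrences, community compositions) so every stage can be
    validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
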