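Package: pvgc
Title: Alignment-Free Polyomavirus Genome Comparison and Annotation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free whole-genome comparison for small circular
    dsDNA viruses such as polyomaviruses. Computes the w-mer pair-count
    similarity statistic S between genome pairs with an exact
    diagonal-rolling algorithm, assigns significance through an extreme
    value (Gumbel) distribution calibrated on shuffled genomes, clusters
    genomes by connected components of the all-vs-all p-value graph at
    user-chosen cutoffs, and profiles per-window conservation of a query
    genome against a database. Companion utilities cover genome curation
    (length filtering, strand correspondence, ambiguity resolution,
    deduplication), viral genome annotation (ORF discovery with AUG/GUG
    starts, origin-of-replication pentanucleotide and palindrome motifs,
    AT-rich tracts, GT-AG splice candidates, synonymous/nonsynonymous
    SNP classification), surveillance tally arithmetic combining PCR and
    serology screening results, and a synthetic genome-family simulator
    used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
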