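Package: kaksScreen
Title: Pairwise Ka/Ks Screening for Positive Selection in Transcriptome
    Ortholog Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale reimplementation of a comparative-transcriptome
    screen for positively selected genes between two species. Starting from
    two transcript sets in FASTA, the pipeline identifies putative
    one-to-one orthologs by six-frame translated similarity search with
    reciprocal best hits, extracts coding sequences from annotation or
    open-reading-frame prediction, builds protein-guided codon alignments,
    estimates Ka, Ks and their ratio per pair with the Nei-Gojobori (1986)
    pathway-counting method and a Yang-Nielsen (2000) style
    kappa/frequency-weighted estimator, filters likely paralogs on Ks,
    classifies candidate genes on Ka/Ks thresholds, and aggregates results
    over Gene Ontology terms including a two-step a-priori functional
    screen. A Goldman-Yang style codon substitution simulator generates
    transcriptome fixtures with known omega, kappa and divergence so every
    stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Software, Genetics, Phylogenetics, SequenceMatching, Alignment
RoxygenNote: 7.3.3
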