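Package: txstratkit
Title: Annotation Toolkit for Non-Model Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale re-usable tooling for annotating de novo
    transcriptome assemblies of non-model organisms: assembly summary
    statistics (N50, length histograms, hit-rate-by-length), sequencing
    saturation analysis by seeded subsampling of read alignments,
    phylostratigraphic assignment of gene origins from taxon-binned
    homology hits with a contamination heuristic, Gene Ontology DAG
    subtree-coverage comparison between species, reciprocal-search gene
    family recovery with a built-in six-frame translated Smith-Waterman
    backend, Enzyme Commission pathway-set comparison with iPath-style
    edge-list export, and a seeded synthetic-fixture generator so every
    stage runs offline with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
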