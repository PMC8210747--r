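Package: satcons
Title: Conservation Analysis of Tandem-Repeat Satellite DNA from Short and
    Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize a conserved satellite DNA family across
    related species: simulation of genomes, short reads and noisy long reads
    with known satellite content; direct monomer extraction from short reads
    with rotation canonicalization and singleton filtering; copy-number and
    variant profiling over a concatenated consensus with single-copy-gene
    normalization; Kimura 2-parameter divergence, repeat landscapes and
    intra/interspecific summary statistics; minimum spanning trees of monomer
    variants; noise-bounded tandem-array detection in error-prone long reads
    with kb/Mb density and flanker clustering; and transcription
    quantification (FPKM, Welch tests, delta-delta-Ct).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ape,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
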