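Package: hopfus
Title: Microsynteny and Intron-Phase Architecture of Convergent Plant Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of the convergently transcribed plant gene
    pair formed by the co-chaperone gene hop and the nuclear gene for the
    chloroplast elongation factor G (chl-fus). Assigns intron phases and
    split codons from annotated gene models, enumerates recombinable
    (symmetric) exon modules, classifies the microsynteny and
    microcolinearity of the gene pair across genomes, classes exon-intron
    topologies into named structure groups, scans intergenic regions for
    instability signatures (interrupted reading frames, MITE-like terminal
    inverted repeats, CACTA-like direct repeats, 3' UTR overlaps), and
    performs hydrophobic cluster analysis of the encoded proteins. Ships a
    deterministic synthetic 53-genome fixture generator so the whole
    pipeline can be exercised end to end without any downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
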