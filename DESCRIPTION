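Package: repeatscape
Title: Repeat Landscapes, Microsatellites and the Comparative Analysis of
    Genome Size Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative genomics of repeat-driven genome size
    variation. Parses RepeatMasker annotations and builds transposable-element
    divergence landscapes with automatic shape classification (L-shaped,
    bimodal, multi-peaked), computes Simpson and Shannon diversity indices of
    TE subclasses, detects perfect and imperfect microsatellites (1-6 bp
    motifs) with standardized motifs and per-Mb abundance/density statistics,
    dates LTR retrotransposon insertions from 5'/3' LTR divergence under the
    Jukes-Cantor correction (T = k/2r), partitions genomes into exonic,
    intronic, intergenic and gap territory from GFF3 annotations, reconstructs
    ancestral states of continuous traits under Brownian motion by maximum
    likelihood, and runs the ordinary least-squares correlation battery
    relating genome size to repeat content, SSR statistics and habitat niche
    width. Includes a seeded synthetic-data generator (genomes with planted TE
    copies, SSR tracts, gene models and N-gaps; LTR pairs of known age;
    Brownian traits on a tree; species panels) so the whole pipeline is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    phytools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
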