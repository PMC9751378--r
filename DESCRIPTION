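Package: orgdyn
Title: Comparative Dynamics of Plant Organelle Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for comparative analysis of plant mitochondrial and
    plastid genomes: microsatellite (SSR) and dispersed forward/palindromic
    repeat scanning, relative synonymous codon usage (RSCU), detection of
    plastome-to-mitogenome transferred fragments (MTPTs) by seed-and-extend
    homology search with interval merging and windowed hotspot calling,
    synteny block extraction, RNA-editing site calling and efficiency
    quantification from read pileups across tissues, sliding-window
    transcription profiles over intergenic spacers with ORF scanning, and
    alignment-matrix site classification (variable, singleton,
    parsimony-informative). A synthetic-data generator plants every feature
    class with a machine-readable truth table so the whole pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
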