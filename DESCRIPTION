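Package: ygenefam
Title: Simulation and Analysis of Ampliconic Y-Chromosome Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multi-copy gene families on mammalian Y
    chromosomes under the birth-and-death model of evolution. Simulates
    amplified two-gene blocks with neutral substitutions and frameshifting
    indels, ampliconic contigs with direct and inverted repeats, and short
    paired-end reads from differentially expressed loci. Provides splice-aware
    pseudogene classification against a reference CDS, locus-specific
    expression quantification from unique read pairs with mismatch-category
    counting and unique-site normalization, Nei-Gojobori synonymous divergence
    (Jukes-Cantor corrected) with neighbor-joining trees and bootstrap
    support, duplication dating by Ks calibration, and word-match dot-plot
    detection of direct/inverted repeat arms plus overlap-based contig
    assembly.
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
    data.table,
    ape,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
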