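Package: cavescreen
Title: Screening Population RNA-Seq Alignments for Fixed Coding Indels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects insertion and deletion variants from spliced RNA-seq
    read alignments and screens them for fixed differences between
    populations. Implements a filter cascade (scaffold size, read depth,
    allele fraction, exon-boundary distance), reading-frame impact
    classification including compound lesions, genomic/cDNA/protein
    coordinate mapping with strand handling, mutation naming, protein
    domain intersection, cross-population sharing classes with outgroup
    polarization of alleles, and gene-to-QTL-marker colocalization
    reports. A deterministic synthetic-fixture generator (toy genome,
    gene models, spliced SAM alignments, truth tables) supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
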