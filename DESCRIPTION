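Package: mitoPCG
Title: Reference-Guided Annotation and Short-Read Recovery of Plant
    Mitochondrial Protein-Coding Genes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for annotating protein-coding genes (PCGs) in plant
    mitochondrial genomes and for recovering their coding sequences from
    Illumina short-read data against a curated reference gene library.
    Implements exon-based transcript grouping for trans-spliced genes,
    pseudogene flagging by exon-count and exon-order rules, GenBank
    transl_except qualifiers for C-to-U RNA-edited start/stop codons,
    notes for non-canonical codons, missing-stop 3' boundary resolution,
    homology-based read-pair extraction, contig-based CDS reconstruction
    with error logging, and concatenated supermatrix construction for
    maximum-likelihood phylogenetics. Ships a deterministic synthetic
    mitogenome, read, and contig simulator so every rule is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
biocViews: Annotation, Alignment, Genetics, Phylogenetics, SequenceMatching
Config/testthat/edition: 3
RoxygenNote: 7.3.3
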