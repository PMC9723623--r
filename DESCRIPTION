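Package: regland
Title: Regulatory-Landscape Analysis from ATAC-Seq Fragments and Histone Marks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of the gene-regulatory landscape of a genome
    from ATAC-seq fragment files, histone post-translational-modification
    (PTM) peak sets, a gene annotation and expression counts. Classifies ATAC
    fragments by size into nucleosome-free (NFR), mono- and di-nucleosome
    classes, calls NFR peaks with a windowed local-Poisson scan, derives
    combinatorial chromatin states from four histone marks, partitions
    regulatory elements into TSS and non-TSS classes, detects transcription
    factor (TF) binding by bias-corrected footprinting over position weight
    matrix (PWM) motif hits, tests phenotype-differential occupancy, and
    assembles a directed TF-TF regulatory network. Includes a synthetic-data
    generator that plants NFRs, chromatin states, footprints and network
    edges with a ground-truth manifest for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
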