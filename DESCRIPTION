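Package: RGeneAtlas
Title: Comparative Annotation and Evolutionary Analysis of Plant
    NBS-LRR Resistance Gene Families
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification, pseudogene classification, phylogenetic
    lineage extraction, locus clustering, cross-genome presence/absence
    and translocation calling, gene-conversion (chimera) detection and
    family-size statistics for plant disease-resistance (NBS-LRR) gene
    families, together with a synthetic multi-genome simulator with a
    machine-readable truth set so every stage of the pipeline can be
    validated against planted events. Implements degenerate-motif
    scanning and in-silico PCR with degenerate primers, Kimura
    two-parameter and p-distance neighbor-joining trees with bootstrap
    support, bidirectional-best-hit orthology with synteny-window
    presence/absence calls, and a zero-mismatch sequence-exchange
    fragment test with permutation p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: Genetics, Annotation, Phylogenetics, ComparativeGenomics,
    SequenceMatching
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RGeneAtlas-package.R'
    'accessors.R'
    'align-utils.R'
    'compare.R'
    'phylo.R'
    'conversion.R'
    'famstats.R'
    'locimap.R'
    'genemodels.R'
    'motifs.R'
    'identify.R'
    'synthio.R'
    'pipeline.R'
    'evaluate.R'
    'formats.R'
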