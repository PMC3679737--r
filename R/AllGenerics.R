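#' @include AllClasses.R
NULL

#' Species label of a genome or truth object
#' @param x a `GenomeAnnotation`.
#' @return character scalar.
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' Gene ranges of a genome
#' @param x a `GenomeAnnotation`.
#' @return `GRanges` with `gene_id` and `ordinal` metadata columns.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Coding sequences of a genome
#' @param x a `GenomeAnnotation`.
#' @return named `DNAStringSet`.
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))

#' Protein sequences of a genome
#' @param x a `GenomeAnnotation`.
#' @return named `AAStringSet`.
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))

#' Gene identifiers of a genome
#' @param x a `GenomeAnnotation`.
#' @return character vector in chromosome/ordinal order.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Gene table of a genome
#'
#' Flat per-gene view (id, chromosome, start, end, strand, ordinal) in
#' chromosome then coordinate order.
#' @param x a `GenomeAnnotation`.
#' @return data.frame.
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' Truth tables of a simulation
#' @param x a `SimulatedTruth`.
#' @return data.frame.
#' @rdname truth-accessors
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))

#' @rdname truth-accessors
#' @export
setGeneric("truthLoci", function(x) standardGeneric("truthLoci"))

#' @rdname truth-accessors
#' @export
setGeneric("truthOrthologs", function(x) standardGeneric("truthOrthologs"))

#' @rdname truth-accessors
#' @export
setGeneric("truthConversions", function(x) standardGeneric("truthConversions"))

#' Exon lengths (aa) of a gene model
#' @param x a `GeneModel`.
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))

#' Intron phases of a gene model
#' @param x a `GeneModel`.
#' @export
setGeneric("intronPhases", function(x) standardGeneric("intronPhases"))

#' Modeled CDS length in nucleotides
#' @param x a `GeneModel`.
#' @export
setGeneric("modelCdsLength", function(x) standardGeneric("modelCdsLength"))
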