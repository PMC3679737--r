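#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a GenomeAnnotation
#'
#' @param species species/genotype label.
#' @param table data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` (1-based inclusive, GFF3 convention).
#' @param cds named `DNAStringSet` (or named character) of CDS.
#' @param proteins named `AAStringSet` (or named character) of proteins.
#'   If missing, proteins are obtained by translating the CDS.
#' @return a validated [GenomeAnnotation-class] with dense per-chromosome
#'   ordinals assigned after coordinate sorting.
#' @examples
#' tab <- data.frame(gene_id = c("g1", "g2"), chromosome = "chr1",
#'                   start = c(1, 500), end = c(300, 900),
#'                   strand = c("+", "-"))
#' cds <- Biostrings::DNAStringSet(c(g1 = "ATGGCTTAA", g2 = "ATGAAATGA"))
#' ga <- genomeAnnotation("toy", tab, cds)
#' geneIds(ga)
#' @export
genomeAnnotation <- function(species, table, cds, proteins = NULL) {
  stopifnot(is.data.frame(table),
            all(c("gene_id", "chromosome", "start", "end", "strand") %in%
                  names(table)))
  table <- table[order(table$chromosome, table$start, table$gene_id), ,
                 drop = FALSE]
  ord <- unlist(lapply(split(seq_len(nrow(table)), table$chromosome),
                       function(i) seq_along(i) - 1L), use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = table$chromosome,
    ranges = IRanges::IRanges(start = table$start, end = table$end),
    strand = table$strand)
  gr$gene_id <- table$gene_id
  gr$ordinal <- ord
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  if (is.null(proteins)) {
    # conceptual translation: frame 1, trailing partial codon dropped
    proteins <- Biostrings::AAStringSet(
      .translateMany(stats::setNames(as.character(cds), names(cds))))
  } else if (is.character(proteins)) {
    proteins <- Biostrings::AAStringSet(proteins)
  }
  missing <- setdiff(table$gene_id, names(cds))
  if (length(missing))
    stop("missing CDS for gene id(s): ", paste(missing, collapse = ", "))
  missing <- setdiff(table$gene_id, names(proteins))
  if (length(missing))
    stop("missing protein for gene id(s): ", paste(missing, collapse = ", "))
  new("GenomeAnnotation", species = species, genes = gr,
      cds = cds[table$gene_id], proteins = proteins[table$gene_id])
}

#' @rdname species
#' @aliases species,GenomeAnnotation-method
setMethod("species", "GenomeAnnotation", function(x) x@species)

#' @rdname genes
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname cdsSeqs
setMethod("cdsSeqs", "GenomeAnnotation", function(x) x@cds)

#' @rdname proteinSeqs
setMethod("proteinSeqs", "GenomeAnnotation", function(x) x@proteins)

#' @rdname geneIds
setMethod("geneIds", "GenomeAnnotation", function(x) x@genes$gene_id)

#' @rdname geneTable
setMethod("geneTable", "GenomeAnnotation", function(x) {
  gr <- x@genes
  data.frame(
    gene_id = gr$gene_id,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ordinal = gr$ordinal,
    stringsAsFactors = FALSE)
})

setMethod("show", "GenomeAnnotation", function(object) {
  tab <- geneTable(object)
  cat("GenomeAnnotation of", object@species, "--", nrow(tab), "genes on",
      length(unique(tab$chromosome)), "chromosome(s)\n")
})

#' @rdname truthGenes
setMethod("truthGenes", "SimulatedTruth", function(x) x@genes)
#' @rdname truthLoci
setMethod("truthLoci", "SimulatedTruth", function(x) x@loci)
#' @rdname truthOrthologs
setMethod("truthOrthologs", "SimulatedTruth", function(x) x@orthologs)
#' @rdname truthConversions
setMethod("truthConversions", "SimulatedTruth", function(x) x@conversions)

setMethod("show", "SimulatedTruth", function(object) {
  cat("SimulatedTruth:", nrow(object@genes), "genes,",
      nrow(object@loci), "locus-species records,",
      nrow(object@orthologs), "ortholog pairs,",
      nrow(object@conversions), "conversion tracts\n")
})

#' Construct a GeneModel
#'
#' @param modelId model label.
#' @param exonLengths exon lengths in amino acids.
#' @param intronPhases intron phases (0/1/2), one per internal junction.
#' @param refCds optional representative intact CDS (character or
#'   `DNAStringSet` of length 1) used as alignment reference when calling
#'   pseudogenes.
#' @param provenance free-text provenance note.
#' @export
geneModel <- function(modelId, exonLengths, intronPhases = integer(0),
                      refCds = NULL, provenance = NA_character_) {
  if (is.character(refCds)) refCds <- Biostrings::DNAStringSet(refCds)
  new("GeneModel", modelId = modelId, exonLengths = as.numeric(exonLengths),
      intronPhases = as.numeric(intronPhases), refCds = refCds,
      provenance = provenance)
}

#' @rdname exonLengths
setMethod("exonLengths", "GeneModel", function(x) x@exonLengths)
#' @rdname intronPhases
setMethod("intronPhases", "GeneModel", function(x) x@intronPhases)
#' @rdname modelCdsLength
setMethod("modelCdsLength", "GeneModel", function(x) {
  if (!is.null(x@refCds) && length(x@refCds))
    Biostrings::width(x@refCds)[1]
  else
    3 * sum(x@exonLengths)
})

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel", object@modelId, "--", length(object@exonLengths),
      "exon(s); phases:",
      if (length(object@intronPhases))
        paste(object@intronPhases, collapse = ",") else "none", "\n")
})
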