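#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' GenomeAnnotation: ordered gene models of one genome
#'
#' Holds the gene complement of one genome as a [GenomicRanges::GRanges]
#' (one range per gene, 1-based inclusive coordinates as in GFF3) together
#' with the CDS and protein sequence of every gene. Genes carry a dense
#' 0-based `ordinal` along each chromosome after coordinate sorting; gene
#' order, not transcript structure, is what the comparative analyses use.
#'
#' @slot species single species/genotype label.
#' @slot genes `GRanges` with metadata columns `gene_id` and `ordinal`.
#' @slot cds named `DNAStringSet` of coding sequences, one per gene.
#' @slot proteins named `AAStringSet` of protein sequences, one per gene.
#'
#' @export
setClass("GenomeAnnotation",
  representation(
    species = "character",
    genes = "GRanges",
    cds = "DNAStringSet",
    proteins = "AAStringSet"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  if (length(object@species) != 1L || is.na(object@species) ||
      !nzchar(object@species))
    msg <- c(msg, "'species' must be a single non-empty string")
  ids <- object@genes$gene_id
  if (is.null(ids))
    return("genes must carry a 'gene_id' metadata column")
  if (anyDuplicated(ids))
    msg <- c(msg, "gene ids must be unique genome-wide")
  if (!setequal(names(object@cds), ids) ||
      !setequal(names(object@proteins), ids))
    msg <- c(msg, "cds/protein names must match gene ids exactly")
  ord <- object@genes$ordinal
  if (is.null(ord)) {
    msg <- c(msg, "genes must carry an 'ordinal' metadata column")
  } else {
    bychr <- split(data.frame(start = GenomicRanges::start(object@genes),
                              ord = ord),
                   as.character(GenomicRanges::seqnames(object@genes)))
    for (chr in names(bychr)) {
      d <- bychr[[chr]]
      d <- d[order(d$start), , drop = FALSE]
      if (!identical(d$ord, seq_len(nrow(d)) - 1L))
        msg <- c(msg, sprintf(
          "ordinals on chromosome '%s' are not dense 0-based ranks of sorted starts",
          chr))
    }
  }
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic multi-genome generator
#'
#' All stochastic features of the generator are controlled here: the shape
#' of each genome (chromosomes, background gene count), the planted R-gene
#' lineages and the LRR-RLK family, the per-branch substitution/indel
#' process, and the per-species event probabilities (lineage loss, locus
#' deletion, translocation, pseudogenizing lesions, gene-conversion
#' tracts). One integer seed drives every draw.
#'
#' @export
setClass("SimulationConfig",
  representation(
    nSpecies = "integer",
    nChromosomes = "integer",
    genesPerChromosome = "integer",
    nRLineages = "integer",
    lineageSizeMean = "numeric",
    substitutionRate = "numeric",
    indelRate = "numeric",
    pLineageLoss = "numeric",
    pLocusDeletion = "numeric",
    pTranslocation = "numeric",
    pPseudogene = "numeric",
    lesionMix = "numeric",
    conversionLineage = "logical",
    tractRange = "numeric",
    nConversionTracts = "integer",
    rlkFamilyCount = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(pLineageLoss = object@pLineageLoss,
             pLocusDeletion = object@pLocusDeletion,
             pTranslocation = object@pTranslocation,
             pPseudogene = object@pPseudogene)
  bad <- names(probs)[is.na(probs) | probs < 0 | probs > 1]
  if (length(bad))
    msg <- c(msg, paste0("probabilities outside [0,1]: ",
                         paste(bad, collapse = ", ")))
  if (length(object@lesionMix) != 3L ||
      !setequal(names(object@lesionMix),
                c("frameshift", "nonsense", "partial")))
    msg <- c(msg,
      "lesionMix must be named proportions for frameshift/nonsense/partial")
  else if (abs(sum(object@lesionMix) - 1) > 1e-8)
    msg <- c(msg, "lesionMix must sum to 1")
  if (any(object@lesionMix < 0)) msg <- c(msg, "lesionMix must be >= 0")
  if (length(object@tractRange) != 2L || object@tractRange[1] < 1 ||
      diff(object@tractRange) < 0)
    msg <- c(msg, "tractRange must be c(min, max) with min >= 1")
  counts <- c(object@nSpecies, object@nChromosomes,
              object@genesPerChromosome, object@nRLineages,
              object@rlkFamilyCount, object@nConversionTracts)
  if (any(is.na(counts)) || any(counts < 0) ||
      object@nSpecies < 1L || object@nChromosomes < 1L)
    msg <- c(msg, "counts must be non-negative (species/chromosomes >= 1)")
  if (object@genesPerChromosome < 1L)
    msg <- c(msg, "genesPerChromosome must be >= 1 (empty genome)")
  if (object@lineageSizeMean <= 0)
    msg <- c(msg, "lineageSizeMean must be positive")
  if (object@substitutionRate < 0 || object@indelRate < 0)
    msg <- c(msg, "rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimulatedTruth: machine-readable record of every planted event
#'
#' @slot genes per-gene labels: species, gene id, ancestral gene id, role
#'   (`r_gene`, `rlk`, `background`), lineage, locus, intact flag and
#'   lesion type.
#' @slot loci per-(locus, species) event record: `retained`, `deleted`
#'   or `translocated`.
#' @slot orthologs symmetric ortholog pairs (stored once, species sorted).
#' @slot conversions planted conversion tracts (species, acceptor, donor,
#'   1-based inclusive bp interval on the acceptor CDS).
#'
#' @export
setClass("SimulatedTruth",
  representation(
    genes = "data.frame",
    loci = "data.frame",
    orthologs = "data.frame",
    conversions = "data.frame",
    config = "SimulationConfig"
  )
)

setValidity("SimulatedTruth", function(object) {
  msg <- character()
  need <- c("species", "gene_id", "ancestral_id", "role", "lineage",
            "locus", "intact", "lesion")
  if (!all(need %in% names(object@genes)))
    msg <- c(msg, "truth gene table is missing columns")
  else if (anyDuplicated(object@genes[c("species", "gene_id")]))
    msg <- c(msg, "every emitted gene must have exactly one label")
  if (nrow(object@conversions)) {
    if (any(object@conversions$start < 1) ||
        any(object@conversions$end < object@conversions$start))
      msg <- c(msg, "conversion tract coordinates malformed")
  }
  if (length(msg)) msg else TRUE
})

#' GeneModel: clade reference exon/intron structure
#'
#' Full-length homologues with an open reading frame in the same clade are
#' expected to share a gene structure (exon count, intron positions and
#' phases); a `GeneModel` records that consensus structure and, when
#' available, a representative intact CDS used as the alignment reference
#' for pseudogene calling.
#'
#' @slot modelId model label (e.g. `"T1-B"`, `"N4"`).
#' @slot exonLengths exon lengths in amino acids, 5' to 3'.
#' @slot intronPhases intron phase (0/1/2) after each exon but the last.
#' @slot refCds optional representative intact CDS (`DNAStringSet` of 1).
#' @slot provenance free-text provenance note per model.
#'
#' @export
setClass("GeneModel",
  representation(
    modelId = "character",
    exonLengths = "numeric",
    intronPhases = "numeric",
    refCds = "DNAStringSetOrNULL",
    provenance = "character"
  ),
  prototype(refCds = NULL, provenance = NA_character_)
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@exonLengths) < 1L)
    msg <- c(msg, "a gene model needs at least one exon")
  if (length(object@intronPhases) != length(object@exonLengths) - 1L)
    msg <- c(msg, "need exactly one intron phase per internal exon junction")
  if (length(object@intronPhases) &&
      !all(object@intronPhases %in% 0:2))
    msg <- c(msg, "intron phases must be 0, 1 or 2")
  if (length(msg)) msg else TRUE
})
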