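#' @include accessors.R align-utils.R
NULL

#' Read a gene-model table
#'
#' TSV with columns `model_id`, `exon_lengths_aa` (comma-separated),
#' `intron_phases` (comma-separated, empty for single-exon models) and
#' optionally `provenance`. The package ships a reference panel of 18
#' Cucurbitaceae R-gene models (one per clade; three closely related
#' TIR models T1-A/B/C differing in 3' exons) in
#' `system.file("extdata", "gene_models_cucurbitaceae.tsv")`; exon sizes
#' there are synthetic stand-ins where the published structure is only
#' qualitatively known, as marked per model in the provenance column.
#'
#' @param path TSV path; default = the shipped reference panel.
#' @return named list of [GeneModel-class].
#' @export
readGeneModels <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_models_cucurbitaceae.tsv",
                        package = "RGeneAtlas", mustWork = TRUE)
  tab <- readTable(path)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    ex <- as.numeric(strsplit(tab$exon_lengths_aa[i], ",")[[1]])
    ph <- if (is.na(tab$intron_phases[i]) ||
              !nzchar(tab$intron_phases[i])) numeric(0)
          else as.numeric(strsplit(as.character(tab$intron_phases[i]),
                                   ",")[[1]])
    geneModel(tab$model_id[i], ex, ph,
              provenance = if ("provenance" %in% names(tab))
                tab$provenance[i] else NA_character_)
  })
  stats::setNames(models, tab$model_id)
}

#' Infer the consensus gene model of a clade
#'
#' Full-length homologues with an open reading frame in the same clade are
#' expected to share their gene structure. Given the observed exon
#' structures of intact members, returns the majority exon count with
#' median exon lengths and majority intron phases, and flags disagreement
#' when members differ in exon count (as when a deletion derivative lost
#' an exon).
#'
#' @param members list of member structures, each a list with
#'   `exonLengths` (aa) and `intronPhases`.
#' @param modelId label for the consensus model.
#' @return list with `model` ([GeneModel-class]) and `disagreement`
#'   (logical).
#' @export
inferGeneModel <- function(members, modelId = "consensus") {
  if (!length(members)) stop("no intact full-length members supplied")
  counts <- vapply(members, function(m) length(m$exonLengths), integer(1))
  tabc <- table(counts)
  majority <- as.integer(names(tabc)[which.max(tabc)])
  disagreement <- length(tabc) > 1L
  sel <- members[counts == majority]
  exlen <- vapply(seq_len(majority), function(e)
    stats::median(vapply(sel, function(m) m$exonLengths[e], numeric(1))),
    numeric(1))
  phases <- if (majority > 1L)
    vapply(seq_len(majority - 1L), function(e) {
      ph <- vapply(sel, function(m) m$intronPhases[e], numeric(1))
      as.numeric(names(which.max(table(ph))))
    }, numeric(1))
  else numeric(0)
  list(model = geneModel(modelId, exlen, phases,
                         provenance = "consensus of intact members"),
       disagreement = disagreement)
}

#' Call a gene intact or pseudogene against its clade model
#'
#' Compares a gene's CDS with the clade reference (an intact clade
#' member's CDS attached to the [GeneModel-class]) and classifies lesions:
#'
#' * `partial`: the local alignment covers less than `min_coverage` of the
#'   modeled CDS (a large deletion/truncation);
#' * `frameshift`: the alignment requires an indel whose length is not a
#'   multiple of 3;
#' * `nonsense`: an in-frame stop codon occurs before the final
#'   `late_stop_tail` fraction of the modeled CDS.
#'
#' A gene with no lesion is `intact`; with no usable reference the verdict
#' is `unassessable`. The coverage and late-stop thresholds are tunable;
#' the defaults treat only large truncations as partial genes and do not
#' penalise stops at (or very near) the native position.
#'
#' @param gene_id gene identifier (for the report).
#' @param cds the gene's CDS (character or `DNAString`).
#' @param model a [GeneModel-class] with a reference CDS (`refCds`).
#' @param min_coverage minimum aligned fraction of the modeled CDS.
#' @param late_stop_tail fraction of the modeled CDS within which a stop
#'   is considered the native stop.
#' @return one-row data.frame: `gene_id`, `verdict`, `lesions`
#'   (comma-separated), `detail`.
#' @export
callPseudogene <- function(gene_id, cds, model, min_coverage = 0.7,
                           late_stop_tail = 0.05) {
  if (is.null(model@refCds) || !length(model@refCds))
    return(data.frame(gene_id = gene_id, verdict = "unassessable",
                      lesions = "", detail = "no intact clade member",
                      stringsAsFactors = FALSE))
  cds <- as.character(cds)
  ref <- as.character(model@refCds[[1]])
  modelLen <- modelCdsLength(model)
  lesions <- character(0)
  detail <- character(0)

  # conservative gap costs: between clade members at ~10% divergence the
  # cheap-gap scoring used for homology search starts placing spurious
  # compensating 1-bp gap pairs; indel calls need gaps only where the
  # sequences demand them
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds), Biostrings::DNAString(ref), type = "local",
    substitutionMatrix = .ntSubstMat(), gapOpening = 5, gapExtension = 2)
  covered <- Biostrings::width(Biostrings::subject(pa)@range)
  if (covered / modelLen < min_coverage) {
    lesions <- c(lesions, "partial")
    detail <- c(detail, sprintf("coverage=%.2f", covered / modelLen))
  }
  insW <- unlist(Biostrings::width(Biostrings::insertion(pa)))
  delW <- unlist(Biostrings::width(Biostrings::deletion(pa)))
  # a frameshift shifts the net reading frame; a compensating
  # insertion/deletion pair (net 0) does not
  netShift <- (sum(insW) - sum(delW)) %% 3L
  if (netShift != 0L && (any(insW %% 3L != 0L) || any(delW %% 3L != 0L))) {
    lesions <- c(lesions, "frameshift")
    detail <- c(detail, sprintf("net_indel=%d", netShift))
  }
  aa <- .translateCds(cds)
  stopAt <- regexpr("*", aa, fixed = TRUE)
  if (stopAt > 0L && (3L * stopAt) < (1 - late_stop_tail) * modelLen) {
    lesions <- c(lesions, "nonsense")
    detail <- c(detail, sprintf("stop@codon%d", stopAt))
  }
  verdict <- if (length(lesions)) "pseudogene" else "intact"
  data.frame(gene_id = gene_id, verdict = verdict,
             lesions = paste(lesions, collapse = ","),
             detail = paste(detail, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Call pseudogenes for every R-gene of a genome
#'
#' Groups candidate R-genes into clades (subfamilies at `threshold`
#' percent nucleotide identity, see [assignSubfamilies()]), builds each
#' clade's reference from its longest motif-complete member, and calls
#' every member against it. Genes in clades with no intact member are
#' `unassessable`.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param candidates candidate table ([identifyCandidates()] +
#'   [findHomologs()]) for that genome.
#' @param subfamilies optional precomputed subfamily table
#'   ([assignSubfamilies()]); may cover several genomes (pooled clades),
#'   in which case clade references can come from other genomes. Computed
#'   from this genome alone if `NULL`.
#' @param ref_cds optional named `DNAStringSet` pool of reference CDS
#'   (defaults to this genome's candidate CDS).
#' @param ref_motif_ids ids within the reference pool that are
#'   motif-complete (eligible as clade references); defaults to this
#'   genome's motif-evidence candidates.
#' @param ... passed to [callPseudogene()].
#' @return data.frame of per-gene calls with a `subfamily` column.
#' @export
callPseudogenes <- function(genome, candidates, subfamilies = NULL,
                            ref_cds = NULL, ref_motif_ids = NULL, ...) {
  rIds <- candidates$gene_id[candidates$class %in% c("TIR", "non-TIR")]
  if (!length(rIds))
    return(data.frame(gene_id = character(), verdict = character(),
                      lesions = character(), detail = character(),
                      subfamily = character(), stringsAsFactors = FALSE))
  cds <- cdsSeqs(genome)[rIds]
  if (is.null(subfamilies)) subfamilies <- assignSubfamilies(cds)
  if (is.null(ref_cds)) ref_cds <- cds
  if (is.null(ref_motif_ids))
    ref_motif_ids <- candidates$gene_id[candidates$class %in%
                                          c("TIR", "non-TIR") &
                                        candidates$evidence == "motif"]
  own <- subfamilies[subfamilies$gene_id %in% rIds, , drop = FALSE]
  out <- lapply(unique(own$subfamily), function(sf) {
    members <- own$gene_id[own$subfamily == sf]
    allMembers <- subfamilies$gene_id[subfamilies$subfamily == sf]
    refCandidates <- intersect(intersect(allMembers, ref_motif_ids),
                               names(ref_cds))
    if (length(refCandidates)) {
      # the clade reference must be a full-length open reading frame:
      # in-frame length and no internal stop (a late frameshift can leave
      # the motif chain intact and even lengthen the CDS)
      seqs <- as.character(ref_cds[refCandidates])
      orf <- nchar(seqs) %% 3L == 0L &
        !grepl("*", .translateMany(seqs), fixed = TRUE)
      if (any(orf)) refCandidates <- refCandidates[orf]
    }
    model <- if (length(refCandidates)) {
      w <- Biostrings::width(ref_cds[refCandidates])
      refId <- refCandidates[order(-w, refCandidates)][1]
      geneModel("clade-ref", nchar(as.character(ref_cds[[refId]])) / 3,
                refCds = as.character(ref_cds[[refId]]))
    } else geneModel("clade-ref", 1)
    do.call(rbind, lapply(members, function(g)
      callPseudogene(g, cds[[g]], model, ...)))
  })
  calls <- do.call(rbind, out)
  calls$subfamily <- own$subfamily[match(calls$gene_id, own$gene_id)]
  rownames(calls) <- NULL
  calls[order(calls$gene_id), ]
}
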