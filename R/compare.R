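#' @include align-utils.R
NULL

#' Best local-alignment hit of every query gene in a subject genome
#'
#' A BLAST-like search: candidate pairs are seeded by shared 12-mers, then
#' scored by Smith-Waterman local alignment (match +1, mismatch -1, gap
#' open -2, extend -1). The best hit is the highest-scoring subject; ties
#' are broken by higher identity, then longer HSP, then lexicographic
#' subject id. Queries with no candidate above `min_score` are absent from
#' the result.
#'
#' @param query,subject [GenomeAnnotation-class] objects, or named
#'   `DNAStringSet`s.
#' @param min_score minimum alignment score to report a hit.
#' @param max_candidates subjects aligned per query: the
#'   `max_candidates` sharing the most seed words (further candidates
#'   share only the short conserved motifs and cannot outscore them).
#' @return data.frame (`query`, `subject`, `hsp_length`, `identity`,
#'   `score`).
#' @export
bestHits <- function(query, subject, min_score = 40, max_candidates = 5L) {
  qs <- if (is(query, "GenomeAnnotation")) cdsSeqs(query) else query
  ss <- if (is(subject, "GenomeAnnotation")) cdsSeqs(subject) else subject
  stopifnot(length(qs) > 0L, length(ss) > 0L)
  cand <- .kmerCandidatePairs(qs, ss)
  if (!nrow(cand))
    return(data.frame(query = character(), subject = character(),
                      hsp_length = integer(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- list()
  for (sub in split(cand, cand$query)) {
    qi <- sub$query[1]
    sub <- sub[order(-sub$share, names(ss)[sub$subject]), , drop = FALSE]
    subjIdx <- utils::head(sub$subject, max_candidates)
    stats <- lapply(subjIdx, function(si)
      alignPair(qs[[qi]], ss[[si]], type = "local", fastpath_min = 0.85))
    score <- vapply(stats, `[[`, numeric(1), "score")
    idy <- vapply(stats, `[[`, numeric(1), "identity")
    hsp <- vapply(stats, `[[`, numeric(1), "length")
    ok <- score >= min_score
    if (!any(ok)) next
    o <- order(-score, -idy, -hsp, names(ss)[subjIdx])
    o <- o[ok[o]][1]
    out[[length(out) + 1L]] <- data.frame(
      query = names(qs)[qi], subject = names(ss)[subjIdx[o]],
      hsp_length = hsp[o], identity = idy[o], score = score[o],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(query = character(), subject = character(),
                      hsp_length = integer(), identity = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Call orthologs by bidirectional best hits
#'
#' A pair (a, b) is orthologous iff a's best hit is b, b's best hit is a,
#' the HSP is longer than `min_hsp` bp and its average nucleotide identity
#' exceeds `min_identity` percent. The result is a partial matching (each
#' gene in at most one pair), reported once per pair.
#'
#' @param hits_ab [bestHits()] of genome A against genome B.
#' @param hits_ba [bestHits()] of genome B against genome A.
#' @param min_hsp HSP length must be strictly greater than this (bp).
#' @param min_identity identity must be strictly greater than this (%).
#' @return data.frame (`gene_a`, `gene_b`, `hsp_length`, `identity`).
#' @export
callOrthologs <- function(hits_ab, hits_ba, min_hsp = 500,
                          min_identity = 80) {
  if (!nrow(hits_ab) || !nrow(hits_ba))
    return(data.frame(gene_a = character(), gene_b = character(),
                      hsp_length = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  back <- hits_ba$subject[match(hits_ab$subject, hits_ba$query)]
  mutual <- !is.na(back) & back == hits_ab$query
  keep <- mutual & hits_ab$hsp_length > min_hsp &
    hits_ab$identity > min_identity
  out <- data.frame(gene_a = hits_ab$query[keep],
                    gene_b = hits_ab$subject[keep],
                    hsp_length = hits_ab$hsp_length[keep],
                    identity = hits_ab$identity[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Locate the syntenic region of a gene in another genome
#'
#' Takes up to `window` flanking genes on each side of the focal gene
#' (fewer at chromosome ends), looks their best hits up in the target
#' genome, and reports the 20-gene ordinal window on one target chromosome
#' holding at least `min_hits` of them (scaled to
#' `ceiling(0.7 * flank count)` when fewer than `2 * window` flanks are
#' available). R-genes can be excluded from the flank set via `exclude`,
#' so a deleted or translocated locus does not erode its own anchoring
#' context.
#'
#' @param gene_id focal gene in the query genome.
#' @param query the query [GenomeAnnotation-class].
#' @param target the target [GenomeAnnotation-class].
#' @param hits [bestHits()] of the query genome against the target.
#' @param window flank genes per side.
#' @param min_hits required co-windowed best hits for a full 2x`window`
#'   flank set.
#' @param exclude gene ids never used as flanks (typically all R-genes).
#' @return list (`chromosome`, `ord_start`, `ord_end`, `start`, `end`,
#'   `n_hits`, `n_flanks`) or `NULL` when no window qualifies.
#' @export
syntenyWindow <- function(gene_id, query, target, hits, window = 10L,
                          min_hits = 14L, exclude = character(0)) {
  tab <- geneTable(query)
  i <- match(gene_id, tab$gene_id)
  if (is.na(i)) stop("unknown gene id: ", gene_id)
  chr <- tab$chromosome[i]
  onChr <- tab[tab$chromosome == chr & !(tab$gene_id %in% exclude), ,
               drop = FALSE]
  onChr <- onChr[order(onChr$ordinal), , drop = FALSE]
  left <- onChr$gene_id[onChr$ordinal < tab$ordinal[i]]
  right <- onChr$gene_id[onChr$ordinal > tab$ordinal[i]]
  flanks <- c(utils::tail(left, window), utils::head(right, window))
  nFlanks <- length(flanks)
  if (!nFlanks) return(NULL)
  need <- if (nFlanks >= 2L * window) min_hits
          else ceiling(0.7 * nFlanks)

  # target gene order is ranked over the same (non-excluded) gene universe
  # as the flanks, so R-gene clusters in the target do not dilute the
  # 20-gene window; the returned interval is in bp
  ttab <- geneTable(target)
  ttab <- ttab[!(ttab$gene_id %in% exclude), , drop = FALSE]
  ttab <- ttab[order(ttab$chromosome, ttab$ordinal), , drop = FALSE]
  ttab$rord <- unlist(lapply(split(seq_len(nrow(ttab)), ttab$chromosome),
                             seq_along), use.names = FALSE)
  hi <- hits[hits$query %in% flanks, , drop = FALSE]
  tIdx <- match(hi$subject, ttab$gene_id)
  tIdx <- tIdx[!is.na(tIdx)]
  if (!length(tIdx)) return(NULL)
  hitPos <- data.frame(chromosome = ttab$chromosome[tIdx],
                       ordinal = ttab$rord[tIdx])
  best <- NULL
  for (tchr in unique(hitPos$chromosome)) {
    ords <- sort(hitPos$ordinal[hitPos$chromosome == tchr])
    for (a in seq_along(ords)) {
      inWin <- ords[ords >= ords[a] & ords <= ords[a] + 19L]
      if (length(inWin) >= need &&
          (is.null(best) || length(inWin) > best$n_hits)) {
        span <- ttab[ttab$chromosome == tchr &
                       ttab$rord >= min(inWin) &
                       ttab$rord <= max(inWin), , drop = FALSE]
        best <- list(chromosome = tchr, ord_start = min(inWin),
                     ord_end = max(inWin), start = min(span$start),
                     end = max(span$end), n_hits = length(inWin),
                     n_flanks = nFlanks)
      }
    }
  }
  best
}

#' Presence/absence or translocation status of a locus in a target genome
#'
#' Statuses (mutually exclusive):
#' * `present`: an orthologue of a locus member lies inside the locus's
#'   syntenic interval in the target;
#' * `translocated`: orthologues exist but only outside the interval;
#' * `absent-deleted`: the syntenic interval exists and holds no
#'   orthologue;
#' * `gap/unassessable`: no syntenic interval was found.
#'
#' @param locus_id locus label (for the report).
#' @param members the locus's member gene ids in the query genome.
#' @param orthologs [callOrthologs()] pairs, `gene_a` = query genome side.
#' @param synteny result of [syntenyWindow()] for the locus
#'   representative (first member), or `NULL`.
#' @param target the target [GenomeAnnotation-class].
#' @return one-row data.frame: `locus`, `target`, `status`,
#'   `interval_chromosome`, `interval_start`, `interval_end` (bp).
#' @export
callPaStatus <- function(locus_id, members, orthologs, synteny, target) {
  orth <- orthologs$gene_b[orthologs$gene_a %in% members]
  mk <- function(status)
    data.frame(locus = locus_id, target = species(target), status = status,
               interval_chromosome = if (is.null(synteny)) NA_character_
                                     else synteny$chromosome,
               interval_start = if (is.null(synteny)) NA_integer_
                                else synteny$start,
               interval_end = if (is.null(synteny)) NA_integer_
                              else synteny$end,
               stringsAsFactors = FALSE)
  if (is.null(synteny)) return(mk("gap/unassessable"))
  if (!length(orth)) return(mk("absent-deleted"))
  ttab <- geneTable(target)
  oi <- match(orth, ttab$gene_id)
  inside <- ttab$chromosome[oi] == synteny$chromosome &
    ttab$start[oi] <= synteny$end & ttab$end[oi] >= synteny$start
  if (any(inside)) mk("present") else mk("translocated")
}
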