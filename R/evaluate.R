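#' @include pipeline.R
NULL

#' Score pipeline output against the planted truth
#'
#' Computes, from one [runPipeline()] result on simulated genomes:
#'
#' * identification sensitivity (intact planted R-genes recovered) and
#'   false-positive rate (background genes called R);
#' * pseudogene-call sensitivity and specificity over the planted R-genes
#'   the pipeline identified;
#' * presence/absence accuracy: for every anchor-genome locus retained in
#'   the anchor and every other species, the called status
#'   (present / absent-deleted / translocated) against the planted event;
#' * subfamily agreement: whether the inferred subfamily partition equals
#'   the planted lineage partition (and the fraction of gene pairs on
#'   which the two partitions agree);
#' * conversion recovery: planted tracts (>= `min_tract` bp) overlapped
#'   >= `min_overlap` of their length by a detected event on the acceptor
#'   sequence.
#'
#' @param run result of [runPipeline()] with a `truth` element.
#' @param min_tract planted tracts shorter than this are not scored.
#' @param min_overlap required overlap fraction of the planted tract.
#' @return named list of metrics.
#' @export
evaluateAgainstTruth <- function(run, min_tract = 300, min_overlap = 0.5) {
  stopifnot(!is.null(run$truth))
  tg <- truthGenes(run$truth)
  out <- list()

  # --- identification -------------------------------------------------------
  cand <- do.call(rbind, lapply(names(run$candidates), function(sp) {
    x <- run$candidates[[sp]]; x$species <- sp; x
  }))
  cand$key <- paste(cand$species, cand$gene_id)
  tg$key <- paste(tg$species, tg$gene_id)
  calledR <- cand$key[cand$class %in% c("TIR", "non-TIR")]
  intactR <- tg$key[tg$role == "r_gene" & tg$intact]
  allR <- tg$key[tg$role == "r_gene"]
  background <- tg$key[tg$role != "r_gene"]
  out$identify_sensitivity <- mean(intactR %in% calledR)
  out$identify_fpr <- mean(background %in% calledR)

  # --- pseudogene calls -------------------------------------------------------
  if (!is.null(run$pseudogenes) && nrow(run$pseudogenes)) {
    pg <- run$pseudogenes
    pg$key <- paste(pg$species, pg$gene_id)
    scored <- pg[pg$key %in% allR & pg$verdict != "unassessable", ,
                 drop = FALSE]
    planted <- !tg$intact[match(scored$key, tg$key)]
    called <- scored$verdict == "pseudogene"
    out$pseudogene_sensitivity <- if (any(planted))
      mean(called[planted]) else NA_real_
    out$pseudogene_specificity <- if (any(!planted))
      mean(!called[!planted]) else NA_real_
    out$pseudogene_n <- nrow(scored)
  }

  # --- presence/absence -------------------------------------------------------
  if (!is.null(run$pa_calls) && nrow(run$pa_calls)) {
    tl <- truthLoci(run$truth)
    # called locus -> planted locus via member genes, per query species
    locusAnc <- unlist(lapply(names(run$loci), function(sp) {
      lmap <- run$loci[[sp]]
      lmap$anc <- tg$locus[match(paste(sp, lmap$gene_id), tg$key)]
      vapply(split(lmap$anc, lmap$locus), function(a) {
        a <- a[!is.na(a)]
        if (length(unique(a)) == 1L) a[1] else NA_character_
      }, character(1))
    }))
    pa <- run$pa_calls
    pa$anc <- locusAnc[pa$locus]
    pa <- pa[!is.na(pa$anc), , drop = FALSE]
    truthStatus <- tl$status[match(paste(pa$anc, pa$target),
                                   paste(tl$locus, tl$species))]
    queryStatus <- tl$status[match(paste(pa$anc, pa$species),
                                   paste(tl$locus, tl$species))]
    # translocation is direction-agnostic: a locus moved in the query
    # genome itself is seen as translocated relative to every retained copy
    expect <- ifelse(truthStatus == "deleted", "absent-deleted",
              ifelse(truthStatus == "translocated" |
                       queryStatus == "translocated",
                     "translocated", "present"))
    ok <- !is.na(expect)
    out$pa_accuracy <- mean(pa$status[ok] == expect[ok])
    out$pa_n <- sum(ok)
  }

  # --- subfamilies vs planted lineages ----------------------------------------
  if (!is.null(run$subfamilies) && nrow(run$subfamilies)) {
    sf <- run$subfamilies
    truthLin <- tg$lineage[match(sf$gene_id, tg$gene_id)]
    keep <- !is.na(truthLin)
    a <- sf$subfamily[keep]; b <- truthLin[keep]
    same <- function(v) outer(v, v, "==")
    pairAgree <- same(a) == same(b)
    n <- length(a)
    out$subfamily_pair_agreement <-
      if (n > 1L) mean(pairAgree[upper.tri(pairAgree)]) else NA_real_
    out$subfamily_partition_equal <-
      identical(unname(split(sf$gene_id[keep], a)[order(
        vapply(split(sf$gene_id[keep], a), min, character(1)))]),
        unname(split(sf$gene_id[keep], b)[order(
          vapply(split(sf$gene_id[keep], b), min, character(1)))]))
  }

  # --- conversion tract recovery -----------------------------------------------
  tc <- truthConversions(run$truth)
  tc <- tc[tc$end - tc$start + 1L >= min_tract, , drop = FALSE]
  if (nrow(tc)) {
    recovered <- vapply(seq_len(nrow(tc)), function(r) {
      ev <- run$conversions
      if (is.null(ev) || !nrow(ev)) return(FALSE)
      hit <- ev[ev$seq_i == tc$acceptor[r] | ev$seq_j == tc$acceptor[r], ,
                drop = FALSE]
      if (!nrow(hit)) return(FALSE)
      ol <- pmax(0, pmin(hit$last_site, tc$end[r]) -
                   pmax(hit$first_site, tc$start[r]) + 1L)
      any(ol >= min_overlap * (tc$end[r] - tc$start[r] + 1L))
    }, logical(1))
    out$conversion_recovered <- sum(recovered)
    out$conversion_planted <- nrow(tc)
  }
  out
}
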