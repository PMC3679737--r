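#' @include motifs.R align-utils.R
NULL

#' Classify one gene from its motif hits
#'
#' A gene is called NBS-LRR when the P-loop, kinase-2 and GLPL motifs occur
#' in that order along the protein; the TIR subclass additionally requires
#' an N-terminal TIR signature before the P-loop. A gene with a kinase
#' motif, at least three LRR repeats and no NB-ARC motif chain is called
#' LRR-RLK. Everything else is `rejected`. For NBS-LRR calls the
#' `nbs_region` (P-loop through the end of GLPL, amino-acid coordinates)
#' is recorded -- the conserved region used for phylogenetic analysis.
#'
#' @param gene_id gene identifier.
#' @param hits motif hits from [scanMotifs()] for that gene's protein.
#' @return one-row data.frame: `gene_id`, `class` (`TIR`, `non-TIR`,
#'   `LRR-RLK`, `rejected`), `nbs_start`, `nbs_end`.
#' @export
classifyCandidate <- function(gene_id, hits) {
  pos1 <- function(m) if (m %in% hits$motif)
    min(hits$position[hits$motif == m]) else NA_integer_
  ploop <- pos1("P-loop"); k2 <- pos1("kinase-2"); glpl <- pos1("GLPL")
  # last GLPL hit after kinase-2 closes the NBS region
  glplAfter <- hits$position[hits$motif == "GLPL" &
                               hits$position > ifelse(is.na(k2), Inf, k2)]
  tir <- pos1("TIR")
  kin <- pos1("kinase")
  nLrr <- sum(hits$motif == "LRR")
  cls <- "rejected"; ns <- NA_integer_; ne <- NA_integer_
  if (!is.na(ploop) && !is.na(k2) && length(glplAfter) &&
      ploop < k2) {
    glpl <- min(glplAfter)
    cls <- if (!is.na(tir) && tir < ploop) "TIR" else "non-TIR"
    ns <- ploop
    ne <- glpl + nchar("CKGLPL") - 1L
  } else if (!is.na(kin) && nLrr >= 3L) {
    cls <- "LRR-RLK"
  }
  data.frame(gene_id = gene_id, class = cls, nbs_start = ns, nbs_end = ne,
             stringsAsFactors = FALSE)
}

#' Flag NBS-LRR and LRR-RLK candidates in a genome
#'
#' Scans every protein for the conserved motifs and classifies it; see
#' [classifyCandidate()]. Use [findHomologs()] afterwards to recruit
#' partial or divergent (pseudogenized) homologues that no longer encode
#' the full motif chain.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param motifs motif table, see [rGeneMotifs()].
#' @return data.frame with one row per gene: `gene_id`, `class`,
#'   `nbs_start`, `nbs_end`, `evidence` (`"motif"`).
#' @export
identifyCandidates <- function(genome, motifs = rGeneMotifs()) {
  prots <- proteinSeqs(genome)
  out <- do.call(rbind, lapply(names(prots), function(id) {
    p <- as.character(prots[[id]])
    if (!nzchar(p))
      return(data.frame(gene_id = id, class = "rejected",
                        nbs_start = NA_integer_, nbs_end = NA_integer_,
                        stringsAsFactors = FALSE))
    classifyCandidate(id, scanMotifs(p, motifs))
  }))
  out$evidence <- ifelse(out$class == "rejected", NA_character_, "motif")
  out
}

#' Recruit partial or divergent homologues of verified candidates
#'
#' Any gene whose CDS aligns locally to a verified candidate CDS with at
#' least `min_identity` percent identity over at least `min_length`
#' aligned bases is added to the candidate set, flagged
#' `"homology-recruited"` and given the class of its best-matching
#' verified candidate. Recruitment reaches a fixed point after one pass
#' over the additions (newly recruited genes also act as baits).
#'
#' @param candidates candidate table from [identifyCandidates()].
#' @param genome the [GenomeAnnotation-class] the candidates came from.
#' @param min_identity minimum percent identity over the aligned region.
#' @param min_length minimum aligned length in bp (the package's
#'   deterministic surrogate for a database e-value cutoff).
#' @return the expanded candidate table.
#' @export
findHomologs <- function(candidates, genome, min_identity = 70,
                         min_length = 150) {
  cds <- cdsSeqs(genome)
  verified <- candidates$gene_id[candidates$class %in%
                                   c("TIR", "non-TIR")]
  if (!length(verified)) return(candidates)
  pool <- candidates$gene_id[candidates$class == "rejected"]
  repeat {
    if (!length(pool)) break
    cand <- .kmerCandidatePairs(cds[pool], cds[verified])
    recruited <- character(0)
    for (i in unique(cand$query)) {
      sub <- cand[cand$query == i, , drop = FALSE]
      # try the baits sharing the most seed words first; three suffice to
      # pick the recruiting class
      subj <- utils::head(sub$subject[order(-sub$share)], 3L)
      best <- NULL
      for (j in subj) {
        al <- alignPair(cds[[pool[i]]], cds[[verified[j]]], type = "local")
        if (al$identity >= min_identity && al$length >= min_length &&
            (is.null(best) || al$score > best$score))
          best <- list(score = al$score, class = candidates$class[
            match(verified[j], candidates$gene_id)])
      }
      if (!is.null(best)) {
        k <- match(pool[i], candidates$gene_id)
        candidates$class[k] <- best$class
        candidates$evidence[k] <- "homology-recruited"
        recruited <- c(recruited, pool[i])
      }
    }
    if (!length(recruited)) break
    verified <- c(verified, recruited)
    pool <- setdiff(pool, recruited)
  }
  candidates
}

#' In-silico PCR with degenerate primers
#'
#' Returns every template substring bounded by a forward-primer match on
#' the plus strand and a reverse-primer match on the minus strand whose
#' length lies within `product_range`. Degenerate positions match per
#' IUPAC (inosine `I` is treated as `N`); at most `max_mismatch`
#' mismatches are tolerated outside the 3' `clamp` bases and none inside
#' them, emulating low-stringency degenerate-primer annealing.
#'
#' @param template nucleotide sequence (character or `DNAString`).
#' @param fwd,rev primer sequences, 5'->3', IUPAC-degenerate; length >= 15.
#' @param product_range allowed product length range in bp (inclusive).
#' @param max_mismatch mismatches tolerated outside the 3' clamp.
#' @param clamp number of 3'-terminal bases that must match exactly.
#' @return data.frame (`start`, `end`, `length`, `fragment`).
#' @export
insilicoPcr <- function(template, fwd, rev, product_range = c(240, 700),
                        max_mismatch = 2L, clamp = 5L) {
  if (nchar(gsub("[^A-Za-z]", "", fwd)) < 15L ||
      nchar(gsub("[^A-Za-z]", "", rev)) < 15L)
    stop("primers must be at least 15 nt long")
  subj <- strsplit(toupper(as.character(template)), "")[[1]]

  fpat <- .parseNtPattern(fwd)
  rpat <- .parseNtPattern(rev)

  siteStarts <- function(pat, clampIdx) {
    m <- length(pat)
    mismAll <- .slideMismatches(subj, pat)
    mismClamp <- .slideMismatches(subj, pat[clampIdx])
    # mismatch counts of the clamp sub-pattern at the clamp's own offsets
    n <- length(subj)
    starts <- seq_len(n - m + 1L)
    offset <- clampIdx[1] - 1L
    cl <- mismClamp[starts + offset]
    which(mismAll - cl <= max_mismatch & cl == 0L)
  }

  m_f <- length(fpat)
  # forward primer: 3' end is its right end
  fHits <- siteStarts(fpat, (m_f - clamp + 1L):m_f)
  # reverse primer anneals to the plus strand as its reverse complement;
  # its 3' end maps to the left end of the match site
  rpatRc <- rev(lapply(rpat, .revcompChars))
  m_r <- length(rpatRc)
  rHits <- siteStarts(rpatRc, seq_len(clamp))

  out <- list()
  for (fs in fHits) for (rs in rHits) {
    pEnd <- rs + m_r - 1L
    len <- pEnd - fs + 1L
    if (rs > fs + m_f - 1L && len >= product_range[1] &&
        len <= product_range[2])
      out[[length(out) + 1L]] <- data.frame(
        start = fs, end = pEnd, length = len,
        fragment = paste(subj[fs:pEnd], collapse = ""),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), fragment = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Collapse near-identical fragments from one PCR reaction
#'
#' Fragments from the same reaction with at least `threshold` percent
#' global nucleotide identity are considered to come from the same gene
#' (single-linkage grouping). One representative per group is returned:
#' the longest fragment, ties broken by lexicographic id.
#'
#' @param fragments named character vector or `DNAStringSet` of fragments
#'   sharing one reaction label.
#' @param threshold percent identity at or above which two fragments are
#'   the same gene.
#' @return data.frame (`id`, `group`, `representative`).
#' @export
dedupFragments <- function(fragments, threshold = 99.5) {
  if (is.character(fragments)) fragments <- Biostrings::DNAStringSet(fragments)
  n <- length(fragments)
  ids <- names(fragments)
  if (is.null(ids)) ids <- sprintf("frag%03d", seq_len(n))
  if (n == 1L)
    return(data.frame(id = ids, group = 1L, representative = TRUE,
                      stringsAsFactors = FALSE))
  # single linkage via union-find over pairs meeting the threshold
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    idy <- alignPair(fragments[[i]], fragments[[j]], type = "global",
                     fastpath_min = 2)$identity
    if (idy >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group <- match(root, sort(unique(root)))
  widths <- Biostrings::width(fragments)
  rep <- logical(n)
  for (g in unique(group)) {
    members <- which(group == g)
    members <- members[order(-widths[members], ids[members])]
    rep[members[1]] <- TRUE
  }
  # deterministic output order: by group then id
  o <- order(group, ids)
  data.frame(id = ids, group = group, representative = rep,
             stringsAsFactors = FALSE)[o, ]
}
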