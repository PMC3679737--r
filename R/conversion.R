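#' @include phylo.R
NULL

#' Polymorphic columns of an alignment
#'
#' Columns with at least two distinct non-gap states among the rows.
#' Columns with more than `max_gap_frac` gapped rows are dropped entirely
#' (treated as unalignable). At least three sequences are required:
#' a sequence exchange between two homologues is undetectable without the
#' context of further homologues.
#'
#' @param aln alignment (`DNAStringSet`, character vector or character
#'   matrix).
#' @param max_gap_frac maximum fraction of gap rows per usable column.
#' @return integer vector of polymorphic column indices (strictly
#'   increasing), with the character matrix attached as attribute
#'   `"matrix"`.
#' @export
polymorphicSites <- function(aln, max_gap_frac = 0.2) {
  m <- .alnToMatrix(aln)
  if (nrow(m) < 3L)
    stop("need at least 3 sequences to assess sequence exchange")
  isGap <- matrix(m %in% .GAP_CHARS, nrow = nrow(m))
  usable <- colMeans(isGap) <= max_gap_frac
  nStates <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[!isGap[, j], j]
    length(unique(v))
  }, integer(1))
  sites <- which(usable & nStates >= 2L)
  attr(sites, "matrix") <- m
  sites
}

# Best run of TRUE in an agreement vector (NA = unusable site for this
# pair, skipped): returns c(sites, span, firstIdx, lastIdx) of the run
# maximising (site count, bp span) lexicographically; runs covering every
# usable site are discarded (an all-agreeing pair is uninformative).
# `pos` gives the alignment column of each profile site.
.bestRun <- function(agree, pos) {
  use <- !is.na(agree)
  a <- agree[use]
  p <- pos[use]
  idx <- which(use)
  n <- length(a)
  if (!n) return(NULL)
  r <- rle(a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths < n)  # full-profile runs discarded
  if (!length(runs)) return(NULL)
  sites <- r$lengths[runs]
  span <- p[ends[runs]] - p[starts[runs]] + 1L
  o <- order(-sites, -span)[1]
  c(sites[o], span[o], idx[starts[runs[o]]], idx[ends[runs[o]]])
}

#' Zero-mismatch candidate fragments for one sequence pair
#'
#' Maximal runs of consecutive polymorphic sites at which sequences `i`
#' and `j` agree, bounded by sites of disagreement or the profile ends
#' ("no mismatch allowed"). A run covering the whole profile is discarded:
#' a globally identical pair carries no exchange information. The fragment
#' score is the run length in polymorphic sites.
#'
#' @param i,j sequence names or indices.
#' @param sites profile from [polymorphicSites()].
#' @param aln the alignment the profile came from.
#' @return data.frame (`seq_i`, `seq_j`, `first_site`, `last_site`
#'   (alignment columns), `n_sites`, `span_bp`), possibly empty.
#' @export
findFragments <- function(i, j, sites, aln) {
  m <- attr(sites, "matrix")
  if (is.null(m)) m <- .alnToMatrix(aln)
  if (is.character(i)) i <- match(i, rownames(m))
  if (is.character(j)) j <- match(j, rownames(m))
  xi <- m[i, sites]; xj <- m[j, sites]
  agree <- ifelse(xi %in% .GAP_CHARS | xj %in% .GAP_CHARS, NA,
                  xi == xj)
  nm <- rownames(m)
  if (is.null(nm)) nm <- paste0("s", seq_len(nrow(m)))
  out <- data.frame(seq_i = character(), seq_j = character(),
                    first_site = integer(), last_site = integer(),
                    n_sites = integer(), span_bp = integer(),
                    stringsAsFactors = FALSE)
  use <- !is.na(agree)
  a <- agree[use]; p <- sites[use]
  n <- length(a)
  if (!n) return(out)
  r <- rle(a)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    if (r$lengths[k] == n) next
    out[nrow(out) + 1L, ] <- list(nm[i], nm[j], p[starts[k]], p[ends[k]],
                                  r$lengths[k],
                                  p[ends[k]] - p[starts[k]] + 1L)
  }
  out
}

# Null distribution of the experiment-wise maximum fragment statistic:
# polymorphic columns are shuffled jointly across rows; per permutation the
# maximum (site count, bp span) over all pairs is recorded. Returns a
# 2-column matrix (sites, span).
.nullMaxScores <- function(agreeMat, pos, n_perm) {
  nPairs <- nrow(agreeMat)
  nSites <- ncol(agreeMat)
  out <- matrix(0L, n_perm, 2L)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nSites)
    best <- c(0L, 0L)
    for (pr in seq_len(nPairs)) {
      r <- .bestRun(agreeMat[pr, perm], pos)
      if (!is.null(r) && (r[1] > best[1] ||
                          (r[1] == best[1] && r[2] > best[2])))
        best <- r[1:2]
    }
    out[b, ] <- best
  }
  out
}

.pairAgreementMatrix <- function(m, sites) {
  nm <- rownames(m)
  if (is.null(nm)) nm <- paste0("s", seq_len(nrow(m)))
  pairs <- utils::combn(order(nm), 2)  # canonical (name-sorted) order
  A <- matrix(NA, ncol(pairs), length(sites))
  for (k in seq_len(ncol(pairs))) {
    xi <- m[pairs[1, k], sites]; xj <- m[pairs[2, k], sites]
    A[k, ] <- ifelse(xi %in% .GAP_CHARS | xj %in% .GAP_CHARS, NA,
                     xi == xj)
  }
  list(A = A, pairs = pairs, names = nm)
}

#' Simulate a null alignment of i.i.d. columns
#'
#' Columns are independent: monomorphic with probability
#' `1 - p_polymorphic` (a random base), otherwise biallelic with the two
#' alleles assigned to rows by fair coin flips. Used to calibrate the
#' conversion test: under this null there is no exchange signal, so the
#' experiment-wise test should reject a fraction alpha of alignments.
#'
#' @param nseq,ncols alignment dimensions.
#' @param p_polymorphic per-column probability of being polymorphic.
#' @return a named `DNAStringSet`.
#' @export
simulateNullAlignment <- function(nseq = 6L, ncols = 240L,
                                  p_polymorphic = 0.35) {
  bases <- c("A", "C", "G", "T")
  m <- matrix("", nseq, ncols)
  for (j in seq_len(ncols)) {
    if (stats::runif(1) < p_polymorphic) {
      al <- sample(bases, 2L)
      m[, j] <- al[1L + (stats::runif(nseq) < 0.5)]
    } else m[, j] <- sample(bases, 1L)
  }
  Biostrings::DNAStringSet(stats::setNames(
    apply(m, 1, paste, collapse = ""), paste0("s", seq_len(nseq))))
}

#' Permutation p-value of a fragment score
#'
#' The p-value is the proportion (with +1/(n_perm+1) smoothing) of
#' column-permuted alignments -- polymorphic columns shuffled jointly
#' across all rows -- whose maximum pairwise fragment statistic is at
#' least the observed one. Using the maximum over all pairs makes the
#' p-value experiment-wise. Ties in the integer site count are broken by
#' the physical bp span of the run, which keeps the statistic's null
#' distribution nearly continuous and the test calibrated.
#'
#' @param score observed fragment score (run length in polymorphic
#'   sites).
#' @param aln the alignment.
#' @param span_bp observed bp span of the run (defaults to 0: most
#'   conservative tie-breaking).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return p-value in (0, 1].
#' @export
permutationPvalue <- function(score, aln, span_bp = 0, n_perm = 1000L,
                              seed = 1L) {
  sites <- polymorphicSites(aln)
  m <- attr(sites, "matrix")
  pm <- .pairAgreementMatrix(m, sites)
  set.seed(seed)
  null <- .nullMaxScores(pm$A, as.integer(sites), n_perm)
  hits <- null[, 1] > score | (null[, 1] == score & null[, 2] >= span_bp)
  (1 + sum(hits)) / (n_perm + 1)
}

#' Detect sequence-exchange (gene conversion) tracts
#'
#' Scans every sequence pair of the alignment for zero-mismatch fragments
#' ([findFragments()]), assigns each fragment an experiment-wise
#' permutation p-value (shared null distribution of the maximum pairwise
#' statistic) and reports fragments with `p < alpha` as conversion
#' events. Tract length is the alignment-column span from the first to the
#' last polymorphic site of the run, inclusive. A chimera painting assigns
#' each reported tract a donor-group label: events whose tracts share a
#' sequence and overlap are given the same group.
#'
#' @param aln alignment with >= 3 sequences.
#' @param alpha experiment-wise significance level.
#' @param n_perm permutations for the null distribution.
#' @param seed RNG seed.
#' @return list with `events` (data.frame: pair, tract, `n_sites` score,
#'   `p`, `significant`), `painting` (data.frame: sequence, start, end,
#'   group), `n_fragments` (significant pairwise fragments) and
#'   `n_events` (deduplicated by identical tract).
#' @export
detectConversions <- function(aln, alpha = 0.05, n_perm = 1000L,
                              seed = 1L) {
  sites <- polymorphicSites(aln)
  m <- attr(sites, "matrix")
  pm <- .pairAgreementMatrix(m, sites)
  frags <- list()
  for (k in seq_len(ncol(pm$pairs))) {
    f <- findFragments(pm$pairs[1, k], pm$pairs[2, k], sites, NULL)
    if (nrow(f)) frags[[length(frags) + 1L]] <- f
  }
  empty <- data.frame(seq_i = character(), seq_j = character(),
                      first_site = integer(), last_site = integer(),
                      n_sites = integer(), span_bp = integer(),
                      p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (!length(frags))
    return(list(events = empty,
                painting = data.frame(sequence = character(),
                                      start = integer(), end = integer(),
                                      group = integer()),
                n_fragments = 0L, n_events = 0L))
  frags <- do.call(rbind, frags)
  set.seed(seed)
  null <- .nullMaxScores(pm$A, as.integer(sites), n_perm)
  frags$p <- vapply(seq_len(nrow(frags)), function(r) {
    hits <- null[, 1] > frags$n_sites[r] |
      (null[, 1] == frags$n_sites[r] & null[, 2] >= frags$span_bp[r])
    (1 + sum(hits)) / (n_perm + 1)
  }, numeric(1))
  frags$significant <- frags$p < alpha
  events <- frags[frags$significant, , drop = FALSE]
  events <- events[order(events$seq_i, events$seq_j, events$first_site), ,
                   drop = FALSE]
  rownames(events) <- NULL

  # chimera painting: merge significant tracts that share a sequence and
  # overlap into one donor group
  painting <- data.frame(sequence = character(), start = integer(),
                         end = integer(), group = integer(),
                         stringsAsFactors = FALSE)
  if (nrow(events)) {
    grp <- seq_len(nrow(events))
    find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
    overlap <- function(a, b)
      events$first_site[a] <= events$last_site[b] &&
      events$first_site[b] <= events$last_site[a]
    shareSeq <- function(a, b)
      length(intersect(c(events$seq_i[a], events$seq_j[a]),
                       c(events$seq_i[b], events$seq_j[b]))) > 0L
    if (nrow(events) > 1L)
      for (a in 1:(nrow(events) - 1L)) for (b in (a + 1L):nrow(events))
        if (overlap(a, b) && shareSeq(a, b)) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) grp[max(ra, rb)] <- min(ra, rb)
        }
    root <- vapply(seq_len(nrow(events)), find, integer(1))
    gid <- match(root, sort(unique(root)))
    painting <- do.call(rbind, lapply(seq_len(nrow(events)), function(r)
      data.frame(sequence = c(events$seq_i[r], events$seq_j[r]),
                 start = events$first_site[r], end = events$last_site[r],
                 group = gid[r], stringsAsFactors = FALSE)))
  }
  nEvents <- nrow(unique(events[, c("first_site", "last_site")]))
  list(events = events, painting = painting,
       n_fragments = nrow(events), n_events = nEvents)
}
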