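#' @include accessors.R
#' @importFrom data.table data.table .N
NULL

# Ungapped identity of two equal-length sequences (fraction).
.hammingIdentity <- function(a, b) {
  ra <- charToRaw(as.character(a))
  rb <- charToRaw(as.character(b))
  if (length(ra) != length(rb)) stop("unequal lengths")
  sum(ra == rb) / length(ra)
}

# Alignment scoring shared by homolog recruitment and best-hit search:
# match +1, mismatch -1, gap open -2, gap extend -1 (a fixed, reproducible
# surrogate for BLASTN defaults).
.SUBST_MAT <- NULL

.ntSubstMat <- function() {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  mat
}

#' Pairwise sequence identity and alignment statistics
#'
#' Computes the identity of one pair of nucleotide sequences by local
#' (Smith-Waterman) or global (Needleman-Wunsch) alignment with a fixed
#' scoring scheme (match +1, mismatch -1, gap open -2, extend -1). For
#' equal-length pairs whose ungapped identity is already >= `fastpath_min`
#' the ungapped comparison is used directly -- at that similarity an
#' optimal gapped alignment cannot change the identity materially and the
#' short-cut keeps genome-scale scans tractable.
#'
#' @param a,b sequences (character, `DNAString`, or length-1 sets).
#' @param type `"local"` or `"global"`.
#' @param fastpath_min minimum ungapped identity (fraction) that triggers
#'   the equal-length fast path; set above 1 to disable.
#' @return list with `identity` (percent over alignment columns),
#'   `length` (alignment columns; the HSP length for local alignments)
#'   and `score`.
#' @export
alignPair <- function(a, b, type = c("local", "global"),
                      fastpath_min = 0.9) {
  type <- match.arg(type)
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) == nchar(b) && nchar(a) > 0L) {
    h <- .hammingIdentity(a, b)
    if (h >= fastpath_min) {
      n <- nchar(a)
      return(list(identity = 100 * h, length = n,
                  score = n * h - n * (1 - h)))
    }
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = .ntSubstMat(), gapOpening = 2, gapExtension = 1)
  len <- Biostrings::nchar(pa)
  list(identity = Biostrings::pid(pa, type = "PID1"),
       length = len, score = Biostrings::score(pa))
}

# Candidate homologous pairs by shared k-mers (BLAST-like seeding).
# Returns a data.frame (query, subject) of index pairs sharing at least
# `min_share` distinct k-mers. With k = 12 unrelated sequences essentially
# never seed, while homologues at >= 80% identity share many words.
.kmerCandidatePairs <- function(seqsA, seqsB, k = 12L, min_share = 3L) {
  kmerTable <- function(seqs, side) {
    n <- Biostrings::width(seqs)
    lst <- lapply(seq_along(seqs), function(i) {
      if (n[i] < k) return(character(0))
      s <- as.character(seqs[[i]])
      unique(substring(s, 1:(n[i] - k + 1L), k:n[i]))
    })
    data.table::data.table(
      kmer = unlist(lst),
      idx = rep(seq_along(seqs), lengths(lst)))
  }
  ta <- kmerTable(seqsA)
  tb <- kmerTable(seqsB)
  if (!nrow(ta) || !nrow(tb))
    return(data.frame(query = integer(), subject = integer()))
  m <- merge(ta, tb, by = "kmer", allow.cartesian = TRUE,
             suffixes = c(".a", ".b"))
  if (!nrow(m)) return(data.frame(query = integer(), subject = integer()))
  cnt <- m[, list(share = .N), by = c("idx.a", "idx.b")]
  cnt <- cnt[cnt$share >= min_share, ]
  data.frame(query = cnt$idx.a, subject = cnt$idx.b, share = cnt$share)
}

#' Mean pairwise nucleotide identity of a sequence set
#'
#' Global-alignment identity averaged over all pairs; used e.g. to
#' summarise the diversity of amplified fragment sets.
#'
#' @param seqs a `DNAStringSet` (>= 2 sequences).
#' @return mean identity in percent.
#' @export
meanPairwiseIdentity <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  ids <- combn(n, 2, function(ij)
    alignPair(seqs[[ij[1]]], seqs[[ij[2]]], type = "global")$identity)
  mean(ids)
}
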