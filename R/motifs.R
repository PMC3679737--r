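#' @include accessors.R
NULL

# Degenerate amino-acid motif syntax: plain residues, [ABC] alternatives,
# '.' (or 'X') matches anything. Patterns are anchored at every offset and
# scored as matched positions / motif length.
.parseAaPattern <- function(pattern) {
  out <- list()
  chars <- strsplit(pattern, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      set <- character()
      while (chars[j] != "]") { set <- c(set, chars[j]); j <- j + 1L }
      out[[length(out) + 1L]] <- set
      i <- j + 1L
    } else if (chars[i] %in% c(".", "X")) {
      out[[length(out) + 1L]] <- "*"
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  out
}

#' Conserved motifs used to recognise NBS-LRR and LRR-RLK proteins
#'
#' The scanner recognises the five conserved NB-ARC motifs the degenerate
#' primers target (kinase-1a/P-loop, kinase-2, NBS-VI, HD/GLPL, NBS-IX),
#' an N-terminal TIR signature, a kinase catalytic motif and a plant LRR
#' repeat consensus. `max_mismatch` is the per-motif mismatch tolerance
#' applied by [scanMotifs()].
#'
#' @return data.frame with columns `motif`, `pattern`, `max_mismatch`,
#'   `role` (`nbs`, `tir`, `rlk`, `lrr`).
#' @examples
#' rGeneMotifs()
#' @export
rGeneMotifs <- function() {
  data.frame(
    motif = c("TIR", "P-loop", "kinase-2", "NBS-VI", "GLPL", "NBS-IX",
              "kinase", "LRR"),
    pattern = c("FL[SN]FRG", "GG[VLMS]GKTT", "[VLI]LDDVW", "FLDIACF",
                "CKGLPL", "FLHIACF", "HRD[LIV]KSSN", "L..L..L.L..N"),
    max_mismatch = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 0L),
    role = c("tir", "nbs", "nbs", "nbs", "nbs", "nbs", "rlk", "lrr"),
    stringsAsFactors = FALSE)
}

#' Scan a protein for degenerate motifs
#'
#' Reports every position where a motif matches with at most its allowed
#' number of mismatches ('.'/'X' positions match anything and never count
#' as mismatches). The score of a hit is matched positions / motif length.
#'
#' @param protein a single protein sequence (character or `AAString`).
#' @param motifs motif table as returned by [rGeneMotifs()].
#' @param max_mismatch optional single override of the per-motif tolerance.
#' @return data.frame (`motif`, `position`, `score`) sorted by position;
#'   zero rows when nothing matches.
#' @examples
#' scanMotifs("MAAGGVGKTTLAAKL")
#' @export
scanMotifs <- function(protein, motifs = rGeneMotifs(), max_mismatch = NULL) {
  protein <- as.character(protein)
  if (!nzchar(protein)) stop("empty protein sequence")
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  res <- vector("list", nrow(motifs))
  for (r in seq_len(nrow(motifs))) {
    pat <- .parseAaPattern(motifs$pattern[r])
    m <- length(pat)
    if (m > n) next
    k <- if (is.null(max_mismatch)) motifs$max_mismatch[r] else max_mismatch
    starts <- seq_len(n - m + 1L)
    mism <- integer(length(starts))
    for (j in seq_len(m)) {
      allowed <- pat[[j]]
      if (identical(allowed, "*")) next
      mism <- mism + !(chars[starts + j - 1L] %in% allowed)
    }
    hit <- which(mism <= k)
    if (length(hit))
      res[[r]] <- data.frame(motif = motifs$motif[r], position = hit,
                             score = (m - mism[hit]) / m,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(motif = character(), position = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  out[order(out$position, out$motif), , drop = FALSE]
}

#' Degenerate primers targeting conserved R-gene motifs
#'
#' The primer panel used for in-silico amplification of R-gene fragments:
#' forward primers anchored at the kinase-1a (P-loop) motif and reverse
#' (antisense) primers at kinase-2, HD/GLPL, NBS-VI and NBS-IX. Inosine
#' (`I`) is treated as fully degenerate (`N`).
#'
#' @return data.frame (`primer`, `motif`, `orientation`, `sequence`).
#' @export
degeneratePrimers <- function() {
  path <- system.file("extdata", "degenerate_primers.tsv",
                      package = "RGeneAtlas", mustWork = TRUE)
  readTable(path)
}

# IUPAC nucleotide sets; I (inosine) treated as N.
.IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T"))

.parseNtPattern <- function(primer) {
  chars <- strsplit(toupper(gsub("[^A-Za-z]", "", primer)), "")[[1]]
  unknown <- setdiff(chars, names(.IUPAC_NT))
  if (length(unknown))
    stop("unknown nucleotide code(s): ", paste(unknown, collapse = ", "))
  lapply(chars, function(ch) .IUPAC_NT[[ch]])
}

# Per-offset mismatch counts of a degenerate pattern along a concrete
# subject; returns an integer vector over all start offsets.
.slideMismatches <- function(subjectChars, pat) {
  m <- length(pat)
  n <- length(subjectChars)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  mism <- integer(length(starts))
  for (j in seq_len(m))
    mism <- mism + !(subjectChars[starts + j - 1L] %in% pat[[j]])
  mism
}

.revcompChars <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev(unname(comp[chars]))
}
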