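#' @include align-utils.R
NULL

#' Cluster CDS into subfamilies by nucleotide identity
#'
#' Single-linkage clustering at `threshold` percent identity: two genes in
#' the same subfamily are connected by a chain of pairs each at or above
#' the threshold. Identity is measured over the best local alignment
#' (requiring at least `min_overlap` aligned bases), so truncated
#' pseudogenes cluster with their full-length relatives -- family
#' membership is about the sequence the genes share, not about length.
#' Candidate pairs are seeded by shared 12-mers (pairs with no shared
#' words sit far below any useful threshold). The result is invariant to
#' input order: genes are processed name-sorted and subfamilies numbered
#' by their first member.
#'
#' @param cds named `DNAStringSet` (or named character vector).
#' @param threshold percent identity at or above which two genes are
#'   linked.
#' @param min_overlap minimum aligned length (bp) for a pair to count.
#' @return data.frame (`gene_id`, `subfamily`); subfamilies partition the
#'   input.
#' @export
assignSubfamilies <- function(cds, threshold = 70, min_overlap = 150) {
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  stopifnot(length(cds) > 0L, !is.null(names(cds)))
  cds <- cds[order(names(cds))]
  n <- length(cds)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    cand <- .kmerCandidatePairs(cds, cds)
    cand <- cand[cand$query < cand$subject, , drop = FALSE]
    # check the most word-sharing pairs first: cheap high-identity merges
    # collapse clusters early; a cluster pair whose best-seeded member
    # pair falls well short of the threshold is not re-tested through
    # weaker pairs
    cand <- cand[order(-cand$share), , drop = FALSE]
    hopeless <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(cand))) {
      i <- cand$query[r]; j <- cand$subject[r]
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      key <- paste(min(ri, rj), max(ri, rj))
      if (!is.null(hopeless[[key]])) next
      al <- alignPair(cds[[i]], cds[[j]], type = "local",
                      fastpath_min = max(0.8, threshold / 100))
      linked <- al$identity >= threshold && al$length >= min_overlap
      if (linked) parent[max(ri, rj)] <- min(ri, rj)
      else if (al$identity < threshold - 5) hopeless[[key]] <- TRUE
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  sf <- match(root, sort(unique(root)))
  data.frame(gene_id = names(cds),
             subfamily = sprintf("SF%02d", sf),
             stringsAsFactors = FALSE)
}

#' Per-species family summary
#'
#' One row per species: total R-genes, TIR and non-TIR counts, subfamily
#' count and mean genes per subfamily (computed as total / subfamily
#' count). A user-supplied `reported_mean` vector, when given, is carried
#' alongside the computed mean rather than replacing it.
#'
#' @param candidates named list (species -> candidate table from
#'   [identifyCandidates()]/[findHomologs()]).
#' @param subfamilies named list (species -> [assignSubfamilies()] table
#'   of that species' R-genes).
#' @param rlk_counts optional named integer vector of LRR-RLK counts.
#' @param reported_mean optional named numeric vector of externally
#'   reported per-subfamily means.
#' @return data.frame, one row per species.
#' @export
familySummary <- function(candidates, subfamilies, rlk_counts = NULL,
                          reported_mean = NULL) {
  out <- do.call(rbind, lapply(names(candidates), function(sp) {
    cand <- candidates[[sp]]
    tir <- sum(cand$class == "TIR")
    nontir <- sum(cand$class == "non-TIR")
    total <- tir + nontir
    nsf <- if (sp %in% names(subfamilies) && nrow(subfamilies[[sp]]))
      length(unique(subfamilies[[sp]]$subfamily)) else 0L
    data.frame(species = sp, total = total, tir = tir, non_tir = nontir,
               subfamilies = nsf,
               mean_per_subfamily = if (nsf) round(total / nsf, 1) else 0,
               rlk = if (!is.null(rlk_counts)) rlk_counts[[sp]]
                     else sum(cand$class == "LRR-RLK"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(reported_mean))
    out$reported_mean <- reported_mean[out$species]
  rownames(out) <- NULL
  out
}

#' Clade sharing across plant families
#'
#' A clade is family-specific when all its members come from one plant
#' family, shared otherwise.
#'
#' @param clade_families data.frame with columns `clade` and `family`
#'   (one row per clade-family incidence, or per member).
#' @return list: `n_clades`, `n_shared`, `n_specific`,
#'   `percent_specific`. The percentage is reported truncated to one
#'   decimal (never shown more precisely than computed: 23 specific of 39
#'   clades is 58.97%, reported as 58.9).
#' @examples
#' # 39 clades of which 16 hold two or three plant families
#' cf <- data.frame(
#'   clade = c(sprintf("S%02d", 1:23), rep(sprintf("M%02d", 1:16), 2)),
#'   family = c(rep("A", 23), rep(c("A", "B"), each = 16)))
#' cladeSharingStats(cf)$percent_specific
#' @export
cladeSharingStats <- function(clade_families) {
  stopifnot(all(c("clade", "family") %in% names(clade_families)))
  nfam <- vapply(split(clade_families$family, clade_families$clade),
                 function(f) length(unique(f)), integer(1))
  n <- length(nfam)
  shared <- sum(nfam > 1L)
  specific <- n - shared
  list(n_clades = n, n_shared = shared, n_specific = specific,
       percent_specific = floor(1000 * specific / n + 1e-9) / 10)
}

#' Pearson correlation of two family-size vectors
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return the product-moment correlation.
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Two-sample t-test on per-subfamily counts
#'
#' Welch's unequal-variance t-test by default; set `pooled = TRUE` for the
#' classical pooled-variance test.
#'
#' @param groupA,groupB numeric vectors (n >= 2 each).
#' @param pooled use pooled variance?
#' @return list (`t`, `df`, `p`).
#' @export
twoSampleT <- function(groupA, groupB, pooled = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(groupA, groupB, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
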