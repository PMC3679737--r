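#' @include accessors.R
NULL

.GAP_CHARS <- c("-", ".", "?")

.alnToMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (is(aln, "XStringSet")) {
    if (length(unique(Biostrings::width(aln))) > 1L)
      stop("sequences are not aligned (unequal lengths)")
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
    return(m)
  }
  if (is.character(aln)) {
    if (length(unique(nchar(aln))) > 1L)
      stop("sequences are not aligned (unequal lengths)")
    m <- do.call(rbind, strsplit(aln, ""))
    rownames(m) <- names(aln)
    return(m)
  }
  stop("unsupported alignment representation")
}

#' p-distance between two aligned amino-acid sequences
#'
#' Differing sites / compared sites; columns where either sequence has a
#' gap are excluded from the comparison.
#'
#' @param a,b equal-length aligned sequences (character or `XString`).
#' @return the proportion of differing compared sites.
#' @examples
#' pDistance("GGVGKTT", "GGMGKTT")  # 1/7
#' @export
pDistance <- function(a, b) {
  x <- strsplit(toupper(as.character(a)), "")[[1]]
  y <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(x) != length(y)) stop("sequences must be aligned (equal length)")
  ok <- !(x %in% .GAP_CHARS) & !(y %in% .GAP_CHARS)
  if (!any(ok)) stop("no comparable columns: distance undefined")
  sum(x[ok] != y[ok]) / sum(ok)
}

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

#' Kimura two-parameter distance between two aligned nucleotide sequences
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` the transition
#' and `Q` the transversion proportion over comparable columns (both bases
#' in ACGT).
#'
#' @param a,b equal-length aligned sequences.
#' @return the K2P distance.
#' @examples
#' # 20 sites, 2 transitions, 1 transversion: P = 0.1, Q = 0.05
#' a <- paste(rep("A", 20), collapse = "")
#' b <- paste(c("G", "G", "C", rep("A", 17)), collapse = "")
#' k2pDistance(a, b)  # 0.1702
#' @export
k2pDistance <- function(a, b) {
  x <- strsplit(toupper(as.character(a)), "")[[1]]
  y <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(x) != length(y)) stop("sequences must be aligned (equal length)")
  ok <- x %in% names(.TRANSITIONS) & y %in% names(.TRANSITIONS)
  n <- sum(ok)
  if (!n) stop("no comparable columns: distance undefined")
  xs <- x[ok]; ys <- y[ok]
  diff <- xs != ys
  P <- sum(diff & ys == .TRANSITIONS[xs]) / n
  Q <- sum(diff & ys != .TRANSITIONS[xs]) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P distance saturated (1-2P-Q or 1-2Q not positive)")
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln alignment (`XStringSet`, character vector or character
#'   matrix with rownames).
#' @param type `"p"` (p-distance, for amino acids) or `"k2p"` (Kimura
#'   two-parameter, for nucleotides).
#' @param saturated for `"k2p"`: `"error"` propagates the saturation
#'   error; `"cap"` substitutes `cap_value` (used inside bootstrap
#'   resampling, where an occasional saturated replicate pair must not
#'   abort the replicate).
#' @param cap_value distance substituted for saturated pairs.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(aln, type = c("p", "k2p"),
                           saturated = c("error", "cap"), cap_value = 5) {
  type <- match.arg(type)
  saturated <- match.arg(saturated)
  m <- .alnToMatrix(aln)
  n <- nrow(m)
  taxa <- rownames(m)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  # vectorized per-pair computation on the character matrix (the string
  # front-ends pDistance/k2pDistance are the reference implementations)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    xi <- m[i, ]; xj <- m[j, ]
    if (type == "p") {
      ok <- !(xi %in% .GAP_CHARS) & !(xj %in% .GAP_CHARS)
      nc <- sum(ok)
      if (!nc) {
        if (saturated == "cap") { D[i, j] <- D[j, i] <- cap_value; next }
        stop("no comparable columns: distance undefined")
      }
      d <- sum(xi[ok] != xj[ok]) / nc
    } else {
      ok <- xi %in% names(.TRANSITIONS) & xj %in% names(.TRANSITIONS)
      nc <- sum(ok)
      w1 <- w2 <- 0
      if (nc) {
        a <- xi[ok]; b <- xj[ok]
        diff <- a != b
        P <- sum(diff & b == .TRANSITIONS[a]) / nc
        Q <- sum(diff & b != .TRANSITIONS[a]) / nc
        w1 <- 1 - 2 * P - Q
        w2 <- 1 - 2 * Q
      }
      if (!nc || w1 <= 0 || w2 <= 0) {
        if (saturated == "cap") { D[i, j] <- D[j, i] <- cap_value; next }
        stop(if (!nc) "no comparable columns: distance undefined"
             else "K2P distance saturated (1-2P-Q or 1-2Q not positive)")
      }
      d <- -0.5 * log(w1 * sqrt(w2))
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]); on an additive
#' matrix the generating topology and branch lengths are recovered
#' exactly.
#'
#' @param D symmetric distance matrix with row/column names.
#' @return an unrooted [ape::phylo] tree.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor-joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  ape::nj(D)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree of the full alignment, then `B` trees from
#' column-resampled alignments, and labels each internal edge with the
#' percentage of replicates containing its bipartition.
#'
#' @param aln alignment (see [distanceMatrix()]).
#' @param B bootstrap replicates.
#' @param type distance type, `"p"` or `"k2p"`.
#' @param seed RNG seed for the resampling.
#' @return a midpoint-rooted `phylo` tree whose `node.label` holds
#'   integer percent supports (the proportion of replicate trees whose
#'   bipartitions contain each node's split).
#' @export
bootstrapSupport <- function(aln, B = 100L, type = c("p", "k2p"),
                             seed = 1L) {
  type <- match.arg(type)
  m <- .alnToMatrix(aln)
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  buildTree <- function(x)
    njTree(distanceMatrix(x, type = type, saturated = "cap"))
  ref <- phangorn::midpoint(buildTree(m))
  set.seed(seed)
  boots <- lapply(seq_len(B), function(b)
    buildTree(m[, sample.int(ncol(m), replace = TRUE), drop = FALSE]))
  class(boots) <- "multiPhylo"
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  lab <- as.integer(round(100 * counts / B))
  # trivial splits (complement of at most one tip) are in every tree
  nt <- length(ref$tip.label)
  sizes <- lengths(phangorn::Descendants(
    ref, (nt + 1L):(nt + ref$Nnode), "tips"))
  lab[sizes >= nt - 1L] <- 100L
  ref$node.label <- lab
  ref
}

#' Extract well-supported, compact clades (lineages)
#'
#' After midpoint rooting, clades are the maximal monophyletic groups with
#' bootstrap support above `min_support` whose maximum within-group
#' pairwise distance does not exceed `distance_cutoff` (alternatively,
#' with `cutoff_semantics = "between"`, whose minimum distance to every
#' taxon outside the group exceeds the cutoff). Taxa not covered by any
#' qualifying clade become singleton clades, so the clade set partitions
#' the taxa.
#'
#' @param tree a supported tree from [bootstrapSupport()].
#' @param D the distance matrix the tree was built from.
#' @param min_support clades require support strictly greater than this.
#' @param distance_cutoff within-clade maximum distance ceiling.
#' @param cutoff_semantics `"within"` (default) or `"between"`.
#' @return data.frame (`clade`, `member`, `support`, `max_distance`),
#'   one row per taxon.
#' @export
extractClades <- function(tree, D, min_support = 80,
                          distance_cutoff = 0.3,
                          cutoff_semantics = c("within", "between")) {
  cutoff_semantics <- match.arg(cutoff_semantics)
  D <- as.matrix(D)
  rooted <- if (ape::is.rooted(tree)) tree
            else phangorn::midpoint(tree, node.labels = "support")
  ntip <- length(rooted$tip.label)
  rootNode <- ntip + 1L
  supports <- suppressWarnings(as.numeric(rooted$node.label))
  qualifies <- function(node) {
    tips <- rooted$tip.label[phangorn::Descendants(rooted, node,
                                                   "tips")[[1]]]
    if (length(tips) < 2L) return(FALSE)
    sup <- if (node == rootNode) 100 else supports[node - ntip]
    if (is.na(sup) || sup <= min_support) return(FALSE)
    if (cutoff_semantics == "within") {
      max(D[tips, tips]) <= distance_cutoff
    } else {
      out <- setdiff(rownames(D), tips)
      !length(out) || min(D[tips, out, drop = FALSE]) > distance_cutoff
    }
  }
  assigned <- character(0)
  clades <- list()
  visit <- function(node) {
    if (node <= ntip) return(invisible())
    if (qualifies(node)) {
      tips <- rooted$tip.label[phangorn::Descendants(rooted, node,
                                                     "tips")[[1]]]
      sup <- if (node == rootNode) 100 else supports[node - ntip]
      clades[[length(clades) + 1L]] <<- list(
        members = sort(tips), support = sup,
        max_distance = max(D[tips, tips]))
      assigned <<- c(assigned, tips)
      return(invisible())
    }
    kids <- rooted$edge[rooted$edge[, 1] == node, 2]
    for (k in kids) visit(k)
    invisible()
  }
  visit(rootNode)
  singles <- setdiff(rooted$tip.label, assigned)
  for (s in sort(singles))
    clades[[length(clades) + 1L]] <- list(members = s, support = NA_real_,
                                          max_distance = 0)
  # stable clade ids: order by first member
  firsts <- vapply(clades, function(cl) cl$members[1], character(1))
  clades <- clades[order(firsts)]
  do.call(rbind, lapply(seq_along(clades), function(i) {
    cl <- clades[[i]]
    data.frame(clade = sprintf("C%02d", i), member = cl$members,
               support = cl$support, max_distance = cl$max_distance,
               stringsAsFactors = FALSE)
  }))
}
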