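#' @include accessors.R
NULL

#' Cluster R-genes into loci
#'
#' Two R-genes separated by no more than `max_intervening` non-R genes
#' (by gene ordinal along the chromosome) belong to the same cluster; the
#' locus set is the transitive closure of that relation. A non-clustering
#' R-gene is a single-copy locus.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param r_gene_ids ids of the genome's R-genes.
#' @param max_intervening maximum number of intervening non-R genes.
#' @return data.frame, one row per member gene: `locus`, `species`,
#'   `chromosome`, `gene_id`, `ordinal`, `type`
#'   (`single-copy`/`cluster`), ordered by chromosome and position.
#' @export
callClusters <- function(genome, r_gene_ids, max_intervening = 8L) {
  tab <- geneTable(genome)
  unknown <- setdiff(r_gene_ids, tab$gene_id)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  r <- tab[tab$gene_id %in% r_gene_ids, , drop = FALSE]
  r <- r[order(r$chromosome, r$ordinal), , drop = FALSE]
  if (!nrow(r))
    return(data.frame(locus = character(), species = character(),
                      chromosome = character(), gene_id = character(),
                      ordinal = integer(), type = character(),
                      stringsAsFactors = FALSE))
  newLocus <- c(TRUE, diff(r$ordinal) - 1L > max_intervening |
                  r$chromosome[-1] != r$chromosome[-nrow(r)])
  grp <- cumsum(newLocus)
  r$locus <- sprintf("%s_locus%02d", species(genome), grp)
  sizes <- table(grp)
  r$type <- ifelse(as.vector(sizes[as.character(grp)]) >= 2L, "cluster",
                   "single-copy")
  r$species <- species(genome)
  rownames(r) <- NULL
  r[, c("locus", "species", "chromosome", "gene_id", "ordinal", "type")]
}

#' Build the cross-genome integrated locus map
#'
#' Anchors every locus of every species onto the anchor genome: anchor
#' loci sit at their own position and carry a per-species status from the
#' presence/absence calls; non-anchor loci whose members are orthologous
#' to an anchor locus are merged into that row; the rest are placed at
#' their syntenic anchor interval (from their own PA call against the
#' anchor) or reported `unanchorable`.
#'
#' @param anchorSpecies species label of the anchor genome.
#' @param loci named list (species -> [callClusters()] table).
#' @param orthologs combined ortholog table with columns `species_a`,
#'   `gene_a`, `species_b`, `gene_b` (as from [callOrthologs()] runs).
#' @param paCalls combined PA-call table ([callPaStatus()] rows) with
#'   columns `locus`, `species` (locus owner), `target`, `status`,
#'   `interval_chromosome`, `interval_start`, `interval_end`.
#' @return data.frame: one row per anchored locus row, with
#'   `anchor_chromosome`, `anchor_position` and one `status_<species>`
#'   column per species.
#' @export
buildIntegratedMap <- function(anchorSpecies, loci, orthologs, paCalls) {
  speciesNames <- names(loci)
  stopifnot(anchorSpecies %in% speciesNames)
  anchorLoci <- loci[[anchorSpecies]]
  rows <- list()

  statusOf <- function(locusId, target) {
    hit <- paCalls$status[paCalls$locus == locusId &
                            paCalls$target == target]
    if (length(hit)) hit[1] else "unassessed"
  }

  geneLocus <- function(sp, gid) {
    l <- loci[[sp]]
    l$locus[match(gid, l$gene_id)]
  }

  coveredNonAnchor <- character(0)
  for (loc in unique(anchorLoci$locus)) {
    sub <- anchorLoci[anchorLoci$locus == loc, , drop = FALSE]
    row <- list(locus = loc, species = anchorSpecies,
                anchor_chromosome = sub$chromosome[1],
                anchor_position = min(sub$ordinal))
    for (sp in speciesNames) {
      st <- if (sp == anchorSpecies) "present" else statusOf(loc, sp)
      row[[paste0("status_", sp)]] <- st
      if (sp != anchorSpecies) {
        # non-anchor loci orthologous to this anchor locus are covered
        ab <- orthologs[(orthologs$species_a == anchorSpecies &
                           orthologs$gene_a %in% sub$gene_id &
                           orthologs$species_b == sp) |
                        (orthologs$species_b == anchorSpecies &
                           orthologs$gene_b %in% sub$gene_id &
                           orthologs$species_a == sp), , drop = FALSE]
        partner <- ifelse(ab$species_a == sp, ab$gene_a, ab$gene_b)
        if (length(partner))
          coveredNonAnchor <- c(coveredNonAnchor,
                                stats::na.omit(geneLocus(sp, partner)))
      }
    }
    rows[[length(rows) + 1L]] <- row
  }

  for (sp in setdiff(speciesNames, anchorSpecies)) {
    for (loc in setdiff(unique(loci[[sp]]$locus), coveredNonAnchor)) {
      pa <- paCalls[paCalls$locus == loc & paCalls$target == anchorSpecies,
                    , drop = FALSE]
      anchored <- nrow(pa) && !is.na(pa$interval_chromosome[1]) &&
        pa$status[1] != "gap/unassessable"
      row <- list(locus = loc, species = sp,
                  anchor_chromosome = if (anchored)
                    pa$interval_chromosome[1] else "unanchored",
                  anchor_position = if (anchored)
                    pa$interval_start[1] else NA_integer_)
      for (s2 in speciesNames) {
        row[[paste0("status_", s2)]] <-
          if (s2 == sp) "present"
          else if (s2 == anchorSpecies) {
            if (nrow(pa)) {
              # from this locus's viewpoint the anchor lacks it
              switch(pa$status[1],
                     "present" = "present",
                     "translocated" = "translocated",
                     "absent-deleted" = "absent-deleted",
                     "gap/unassessable" = "unanchorable")
            } else "unassessed"
          } else "unassessed"
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}
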