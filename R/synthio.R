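#' @include motifs.R align-utils.R
NULL

# ---------------------------------------------------------------------------
# Sequence building blocks
# ---------------------------------------------------------------------------

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.STOPS <- c("TAA", "TAG", "TGA")

.codonTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

# Encode a protein (character vector of residues, no 'M' prepended, no
# stop) as a CDS: ATG + random synonymous codons + TAA.
.encodeProtein <- function(aa) {
  tab <- .codonTable()
  flat <- unlist(tab, use.names = FALSE)
  nopt <- lengths(tab)
  offset <- stats::setNames(cumsum(nopt) - nopt, names(tab))
  pick <- floor(stats::runif(length(aa)) * nopt[aa]) + 1L
  c("ATG", flat[offset[aa] + pick], "TAA")
}

.codonsToString <- function(codons) paste(codons, collapse = "")

.splitCodons <- function(cds) {
  chars <- strsplit(cds, "")[[1]]
  apply(matrix(chars, nrow = 3), 2, paste, collapse = "")
}

# Substitute bases at `rate` per site, leaving `protect` (nt indices)
# untouched and reverting any codon that a substitution would turn into an
# in-frame stop, so intact genes stay open reading frames.
.mutateCds <- function(cds, rate, protect = integer(0)) {
  if (rate <= 0) return(cds)
  chars <- strsplit(cds, "")[[1]]
  n <- length(chars)
  idx <- setdiff(which(stats::runif(n) < rate), protect)
  if (!length(idx)) return(cds)
  orig <- chars
  bases <- c("A", "C", "G", "T")
  chars[idx] <- vapply(chars[idx], function(b)
    sample(setdiff(bases, b), 1L), character(1))
  # revert codons that became premature stops
  ncod <- n %/% 3L
  if (ncod > 1L) {
    starts <- seq.int(1L, by = 3L, length.out = ncod - 1L)  # internal codons
    cod <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    bad <- which(cod %in% .STOPS)
    for (b in bad) {
      i <- starts[b]:(starts[b] + 2L)
      chars[i] <- orig[i]
    }
  }
  paste(chars, collapse = "")
}

.translateCds <- function(cds) .translateMany(cds)[1]

# vectorized conceptual translation: frame 1, trailing partial codon
# dropped, terminal stop stripped (internal stops kept as '*')
.translateMany <- function(cds) {
  keep <- (nchar(cds) %/% 3L) * 3L
  aa <- character(length(cds))
  ok <- keep > 0L
  if (any(ok)) {
    aaOk <- as.character(suppressWarnings(Biostrings::translate(
      Biostrings::DNAStringSet(substr(cds[ok], 1L, keep[ok])),
      if.fuzzy.codon = "X", no.init.codon = TRUE)))
    aa[ok] <- sub("\\*$", "", aaOk)
  }
  names(aa) <- names(cds)
  aa
}

.randomAa <- function(n) sample(.AA20, n, replace = TRUE)

.lrrRepeat <- function() {
  # plant LRR consensus L..L..L.L..N + 4 free residues
  c("L", .randomAa(2), "L", .randomAa(2), "L", .randomAa(1), "L",
    .randomAa(2), "N", .randomAa(4))
}

# R-protein scaffold: segment layout with the five NB-ARC motifs in order
# and an N-terminal TIR signature. Returns residues (without leading M),
# the protected aa positions (motif anchors) and segment coordinates.
.rProteinScaffold <- function() {
  segs <- list(
    npad = .randomAa(20),
    tir = strsplit("FLSFRG", "")[[1]],
    tirspacer = .randomAa(30),
    ploop = strsplit("GGVGKTT", "")[[1]],
    s1 = .randomAa(95),
    k2 = strsplit("VLDDVW", "")[[1]],
    s2 = .randomAa(55),
    nbs6 = strsplit("FLDIACF", "")[[1]],
    s3 = .randomAa(55),
    glpl = strsplit("CKGLPL", "")[[1]],
    s4 = .randomAa(20),
    nbs9 = strsplit("FLHIACF", "")[[1]],
    s5 = .randomAa(15),
    lrr = unlist(replicate(5, .lrrRepeat(), simplify = FALSE)),
    cpad = .randomAa(10))
  lens <- lengths(segs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  names(starts) <- names(ends) <- names(segs)
  protectedSegs <- c("tir", "ploop", "k2", "nbs6", "glpl", "nbs9")
  protAa <- unlist(lapply(protectedSegs, function(s) starts[s]:ends[s]),
                   use.names = FALSE)
  list(aa = unlist(segs, use.names = FALSE), starts = starts, ends = ends,
       protectedAa = protAa)
}

.rlkProteinScaffold <- function() {
  segs <- list(
    npad = .randomAa(20),
    lrr = unlist(replicate(6, .lrrRepeat(), simplify = FALSE)),
    s1 = .randomAa(20),
    kin = strsplit("HRDLKSSN", "")[[1]],
    s2 = .randomAa(45),
    cpad = .randomAa(10))
  lens <- lengths(segs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  names(starts) <- names(ends) <- names(segs)
  protAa <- c(starts["lrr"]:ends["lrr"], starts["kin"]:ends["kin"])
  list(aa = unlist(segs, use.names = FALSE), starts = starts, ends = ends,
       protectedAa = unname(protAa))
}

# aa position (in the scaffold, which sits after the start codon) -> CDS
# nucleotide indices; +1 codon offset for the leading ATG.
.aaToNt <- function(aaPos) {
  as.vector(vapply(aaPos, function(p) (3L * p + 1L):(3L * p + 3L),
                   integer(3)))
}

# Background genes are random ORFs guaranteed motif-free by rejection
# sampling, so identification tests have a clean negative class.
.randomBackgroundCds <- function(minAa = 160L, maxAa = 240L,
                                 motifs = rGeneMotifs()) {
  repeat {
    aa <- .randomAa(sample(minAa:maxAa, 1L))
    prot <- paste(c("M", aa), collapse = "")
    hits <- scanMotifs(prot, motifs)
    core <- hits[hits$motif != "LRR", , drop = FALSE]
    if (nrow(core) == 0L && sum(hits$motif == "LRR") < 3L)
      return(.codonsToString(.encodeProtein(aa)))
  }
}

# ---------------------------------------------------------------------------
# Config + exported sequence-editing operations
# ---------------------------------------------------------------------------

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' three genomes sharing an ancestral gene order, 12 planted R-gene
#' lineages of mean size 4 (mirroring a small R-gene complement distributed
#' over single-copy and clustered loci), 4% per-branch nucleotide
#' divergence, frequent lineage loss, occasional locus deletion and rare
#' translocation, roughly half of R-gene copies pseudogenized, one
#' conversion-active ("Type I") lineage with three planted exchange tracts,
#' and an LRR-RLK family whose size co-varies with the R-gene complement.
#'
#' @param nSpecies,nChromosomes,genesPerChromosome genome shape.
#' @param nRLineages,lineageSizeMean planted R-gene lineages and their mean
#'   copy number (1 + Poisson(`lineageSizeMean` - 1)).
#' @param substitutionRate per-branch substitutions/site.
#' @param indelRate per-site rate of codon-sized (3 bp) indels applied to
#'   background genes; 0 keeps all genes alignment-free.
#' @param pLineageLoss,pLocusDeletion,pTranslocation,pPseudogene per-species
#'   event probabilities.
#' @param lesionMix named proportions over frameshift/nonsense/partial.
#' @param conversionLineage plant gene-conversion tracts in the largest
#'   lineage?
#' @param tractRange conversion tract length range in bp.
#' @param nConversionTracts number of planted tracts.
#' @param rlkFamilyCount ancestral LRR-RLK family size.
#' @param seed integer seed driving every draw.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nSpecies = 3L, nChromosomes = 4L,
                             genesPerChromosome = 60L, nRLineages = 12L,
                             lineageSizeMean = 4, substitutionRate = 0.04,
                             indelRate = 0, pLineageLoss = 0.15,
                             pLocusDeletion = 0.1, pTranslocation = 0.05,
                             pPseudogene = 0.45,
                             lesionMix = c(frameshift = 0.4, nonsense = 0.3,
                                           partial = 0.3),
                             conversionLineage = TRUE,
                             tractRange = c(300, 1200),
                             nConversionTracts = 3L,
                             rlkFamilyCount = 12L, seed = 1L) {
  new("SimulationConfig",
      nSpecies = as.integer(nSpecies),
      nChromosomes = as.integer(nChromosomes),
      genesPerChromosome = as.integer(genesPerChromosome),
      nRLineages = as.integer(nRLineages),
      lineageSizeMean = lineageSizeMean,
      substitutionRate = substitutionRate,
      indelRate = indelRate,
      pLineageLoss = pLineageLoss,
      pLocusDeletion = pLocusDeletion,
      pTranslocation = pTranslocation,
      pPseudogene = pPseudogene,
      lesionMix = lesionMix[c("frameshift", "nonsense", "partial")],
      conversionLineage = conversionLineage,
      tractRange = as.numeric(tractRange),
      nConversionTracts = as.integer(nConversionTracts),
      rlkFamilyCount = as.integer(rlkFamilyCount),
      seed = as.integer(seed))
}

#' Overwrite a tract of an acceptor CDS with donor sequence
#'
#' Models a gene-conversion event: the returned sequence equals the
#' acceptor outside `[start, end]` (1-based, inclusive) and the donor
#' inside it.
#'
#' @param acceptor,donor CDS sequences (character or `DNAString`);
#'   coordinates must be comparable (aligned / equal length).
#' @param start,end tract bounds, 1-based inclusive; must lie within both
#'   sequences.
#' @return character CDS.
#' @export
plantConversion <- function(acceptor, donor, start, end) {
  acceptor <- as.character(acceptor); donor <- as.character(donor)
  if (start < 1 || end < start || end > nchar(acceptor) ||
      end > nchar(donor))
    stop("conversion tract [", start, ",", end,
         "] outside sequence bounds")
  paste0(substr(acceptor, 1, start - 1),
         substr(donor, start, end),
         substr(acceptor, end + 1, nchar(acceptor)))
}

#' Apply a pseudogenizing lesion to a CDS
#'
#' * `nonsense`: the codon at `position` becomes a random stop codon.
#' * `frameshift`: 1-2 bases are inserted or deleted at the first base of
#'   that codon.
#' * `partial`: the CDS is truncated to `ceiling((1 - cut) * length)`
#'   bases (3' deletion); `cut` must be >= 0.3.
#'
#' @param cds CDS (character or `DNAString`).
#' @param lesion one of `"frameshift"`, `"nonsense"`, `"partial"`.
#' @param position 1-based codon index at which the lesion is applied.
#' @param cut fraction of the CDS removed by a `partial` lesion.
#' @return character CDS.
#' @export
applyLesion <- function(cds, lesion = c("frameshift", "nonsense", "partial"),
                        position, cut = 0.5) {
  lesion <- match.arg(lesion)
  cds <- as.character(cds)
  ncod <- nchar(cds) %/% 3L
  if (position < 1 || position > ncod)
    stop("lesion position ", position, " beyond CDS (", ncod, " codons)")
  base <- 3L * (position - 1L) + 1L
  switch(lesion,
    nonsense = paste0(substr(cds, 1, base - 1), sample(.STOPS, 1L),
                      substr(cds, base + 3L, nchar(cds))),
    frameshift = {
      nb <- sample(1:2, 1L)
      if (stats::runif(1) < 0.5) {
        ins <- paste(sample(c("A", "C", "G", "T"), nb, TRUE), collapse = "")
        paste0(substr(cds, 1, base - 1), ins,
               substr(cds, base, nchar(cds)))
      } else {
        paste0(substr(cds, 1, base - 1),
               substr(cds, base + nb, nchar(cds)))
      }
    },
    partial = {
      if (cut < 0.3) stop("partial lesion must remove >= 30% of the CDS")
      substr(cds, 1, ceiling((1 - cut) * nchar(cds)))
    })
}

# ---------------------------------------------------------------------------
# Genome simulation
# ---------------------------------------------------------------------------

.DUP_DIVERGENCE <- 0.03     # divergence of within-locus duplicates
.LINEAGE_DIVERGENCE <- 0.25 # per-lineage divergence from the master scaffold
.GENE_SPACER <- 200L        # intergenic spacer (bp) when laying coordinates

# replace the TIR segment of a non-TIR lineage ancestor with random sense
# codons that do not resemble the TIR motif
.stripTir <- function(cds, scaffold) {
  aaPos <- scaffold$starts["tir"]:scaffold$ends["tir"]
  repeat {
    repl <- .randomAa(length(aaPos))
    if (nrow(scanMotifs(paste(repl, collapse = ""),
                        rGeneMotifs()[rGeneMotifs()$motif == "TIR", ])) == 0L)
      break
  }
  chars <- strsplit(cds, "")[[1]]
  tab <- .codonTable()
  for (i in seq_along(aaPos)) {
    opts <- tab[[repl[i]]]
    nt <- .aaToNt(aaPos[i])
    chars[nt] <- strsplit(opts[sample.int(length(opts), 1L)], "")[[1]]
  }
  paste(chars, collapse = "")
}

#' Simulate multi-species genomes with planted R-gene family structure
#'
#' Generates `nSpecies` genomes descending star-wise from one ancestral
#' gene order: background genes, an LRR-RLK family, and `nRLineages`
#' R-gene lineages occupying one or two clustered loci each. Per species,
#' whole lineages are lost, individual loci deleted or translocated,
#' individual copies pseudogenized (frameshift / nonsense / partial), and
#' -- in the designated conversion lineage -- sequence tracts are exchanged
#' between copies. Intact genes carry the conserved NBS motifs in frame
#' and evolve without indels, so homologous simulated genes are directly
#' comparable column-by-column. Everything planted is recorded in a
#' [SimulatedTruth-class].
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `genomes` (list of
#'   [GenomeAnnotation-class]) and `truth` ([SimulatedTruth-class]).
#' @examples
#' sim <- simulateGenomes(simulationConfig(nRLineages = 3L,
#'   nChromosomes = 2L, genesPerChromosome = 30L, seed = 7L))
#' sim$genomes[[1]]
#' @export
simulateGenomes <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)

  nSp <- config@nSpecies
  nChr <- config@nChromosomes
  gpc <- config@genesPerChromosome
  L <- config@nRLineages

  # --- ancestral R lineages -------------------------------------------------
  scaffold <- .rProteinScaffold()
  masterCds <- .codonsToString(.encodeProtein(scaffold$aa))
  protectNt <- c(1:3, .aaToNt(scaffold$protectedAa),
                 (nchar(masterCds) - 2L):nchar(masterCds))
  nTir <- if (L > 0L) max(1L, round(0.4 * L)) else 0L
  lineages <- vector("list", L)
  for (l in seq_len(L)) {
    anc <- .mutateCds(masterCds, .LINEAGE_DIVERGENCE, protectNt)
    tir <- l <= nTir
    if (!tir) anc <- .stripTir(anc, scaffold)
    m <- 1L + stats::rpois(1L, max(config@lineageSizeMean - 1, 0))
    copies <- vapply(seq_len(m), function(k)
      .mutateCds(anc, .DUP_DIVERGENCE, protectNt), character(1))
    nLoci <- if (m >= 3L && stats::runif(1) < 0.4) 2L else 1L
    locusOf <- if (nLoci == 2L)
      rep(1:2, c(ceiling(m / 2), floor(m / 2))) else rep(1L, m)
    lineages[[l]] <- list(id = l, tir = tir, copies = copies,
                          locusOf = locusOf, nLoci = nLoci)
  }
  lociDf <- do.call(rbind, lapply(lineages, function(ln) {
    if (is.null(ln)) return(NULL)
    data.frame(lineage = ln$id, locusIdx = seq_len(ln$nLoci),
               stringsAsFactors = FALSE)
  }))
  if (is.null(lociDf))
    lociDf <- data.frame(lineage = integer(), locusIdx = integer())
  if (nrow(lociDf))
    lociDf$locus <- sprintf("L%02d%s", lociDf$lineage,
                            letters[lociDf$locusIdx])

  # --- ancestral background + RLK genes ------------------------------------
  bgCds <- replicate(nChr * gpc, .randomBackgroundCds())
  rlkScaffold <- .rlkProteinScaffold()
  rlkMaster <- .codonsToString(.encodeProtein(rlkScaffold$aa))
  rlkProtect <- c(1:3, .aaToNt(rlkScaffold$protectedAa),
                  (nchar(rlkMaster) - 2L):nchar(rlkMaster))
  rlkCds <- vapply(seq_len(config@rlkFamilyCount), function(k)
    .mutateCds(rlkMaster, 0.15, rlkProtect), character(1))

  # --- ancestral layout ------------------------------------------------------
  # Anchor slots leave >= 11 background genes on each side and keep
  # distinct loci >= 9 background genes apart so loci never merge under
  # the <= 8 intervening-gene rule.
  if (gpc >= 24L) {
    slotPos <- seq(12L, gpc - 12L, by = 9L)
  } else slotPos <- integer(0)
  slots <- expand.grid(chr = seq_len(nChr), pos = slotPos)
  if (nrow(lociDf) > nrow(slots))
    stop("configuration error: ", nrow(lociDf), " R-gene loci but only ",
         nrow(slots), " placement slots; increase genesPerChromosome ",
         "or nChromosomes")
  if (nrow(lociDf)) {
    pick <- sample.int(nrow(slots), nrow(lociDf))
    lociDf$chr <- slots$chr[pick]
    lociDf$pos <- slots$pos[pick]
  }
  rlkChr <- sample.int(nChr, config@rlkFamilyCount, replace = TRUE)
  rlkPos <- sample.int(gpc, config@rlkFamilyCount, replace = TRUE)

  # ancestral gene catalogue: one row per ancestral gene
  anc <- list()
  for (chr in seq_len(nChr)) {
    for (i in seq_len(gpc)) {
      anc[[length(anc) + 1L]] <- list(
        id = sprintf("anc_bg_c%d_%03d", chr, i), role = "background",
        lineage = NA_integer_, locus = NA_character_,
        cds = bgCds[(chr - 1L) * gpc + i], chr = chr, pos = i, sub = 0L)
      hereR <- which(lociDf$chr == chr & lociDf$pos == i)
      for (r in hereR) {
        ln <- lineages[[lociDf$lineage[r]]]
        members <- which(ln$locusOf == lociDf$locusIdx[r])
        for (k in seq_along(members)) {
          anc[[length(anc) + 1L]] <- list(
            id = sprintf("anc_r_l%02d_%d", ln$id, members[k]),
            role = "r_gene", lineage = ln$id, locus = lociDf$locus[r],
            cds = ln$copies[members[k]], chr = chr, pos = i, sub = k)
        }
      }
      hereK <- which(rlkChr == chr & rlkPos == i)
      for (k in hereK) {
        anc[[length(anc) + 1L]] <- list(
          id = sprintf("anc_rlk_%02d", k), role = "rlk",
          lineage = NA_integer_, locus = NA_character_,
          cds = rlkCds[k], chr = chr, pos = i, sub = 100L + k)
      }
    }
  }
  ancDf <- data.frame(
    id = vapply(anc, `[[`, character(1), "id"),
    role = vapply(anc, `[[`, character(1), "role"),
    lineage = vapply(anc, `[[`, integer(1), "lineage"),
    locus = vapply(anc, `[[`, character(1), "locus"),
    chr = vapply(anc, `[[`, integer(1), "chr"),
    pos = vapply(anc, `[[`, integer(1), "pos"),
    sub = vapply(anc, `[[`, integer(1), "sub"),
    stringsAsFactors = FALSE)
  ancCds <- vapply(anc, `[[`, character(1), "cds")
  names(ancCds) <- ancDf$id

  convLineage <- NA_integer_
  if (config@conversionLineage && L > 0L) {
    sizes <- vapply(lineages, function(ln) length(ln$copies), integer(1))
    convLineage <- which.max(sizes)
  }

  # --- per-species evolution -------------------------------------------------
  speciesNames <- sprintf("sp%02d", seq_len(nSp))
  genomes <- vector("list", nSp)
  truthGenesL <- list()
  truthLociL <- list()
  convRows <- list()
  geneIdMap <- list()  # per species: ancestral id -> species gene id

  for (s in seq_len(nSp)) {
    sp <- speciesNames[s]
    cds <- vapply(seq_len(nrow(ancDf)), function(i) {
      prot <- if (ancDf$role[i] == "r_gene") protectNt
              else if (ancDf$role[i] == "rlk") rlkProtect else c(1:3)
      .mutateCds(ancCds[i], config@substitutionRate, prot)
    }, character(1))
    names(cds) <- ancDf$id
    if (config@indelRate > 0) {
      for (i in which(ancDf$role == "background")) {
        nev <- stats::rpois(1L, config@indelRate * nchar(cds[i]))
        for (e in seq_len(nev)) {
          ncod <- nchar(cds[i]) %/% 3L
          at <- 3L * (sample.int(ncod - 2L, 1L)) + 1L
          if (stats::runif(1) < 0.5) {
            ins <- .codonsToString(.encodeProtein(.randomAa(1)))
            ins <- substr(ins, 4, 6)
            cds[i] <- paste0(substr(cds[i], 1, at - 1), ins,
                             substr(cds[i], at, nchar(cds[i])))
          } else {
            cds[i] <- paste0(substr(cds[i], 1, at - 1),
                             substr(cds[i], at + 3L, nchar(cds[i])))
          }
        }
      }
    }

    # lineage loss / locus deletion / translocation
    lociS <- lociDf
    if (nrow(lociS)) {
      lociS$status <- "retained"
      lociS$tchr <- NA_integer_
      lociS$tpos <- NA_integer_
      lostLineage <- vapply(seq_len(L), function(l) {
        isConv <- !is.na(convLineage) && l == convLineage
        !isConv && stats::runif(1) < config@pLineageLoss
      }, logical(1))
      for (r in seq_len(nrow(lociS))) {
        l <- lociS$lineage[r]
        if (lostLineage[l]) { lociS$status[r] <- "deleted"; next }
        if (!is.na(convLineage) && l == convLineage) next
        u <- stats::runif(1)
        if (u < config@pLocusDeletion) lociS$status[r] <- "deleted"
        else if (u < config@pLocusDeletion + config@pTranslocation)
          lociS$status[r] <- "translocated"
      }
      # translocation targets: a random slot on another chromosome, away
      # from every ancestral locus slot
      for (r in which(lociS$status == "translocated")) {
        otherChr <- setdiff(seq_len(nChr), lociS$chr[r])
        tchr <- if (length(otherChr)) sample(otherChr, 1L) else lociS$chr[r]
        cand <- setdiff(slotPos, lociDf$pos[lociDf$chr == tchr])
        if (!length(cand)) cand <- slotPos
        lociS$tchr[r] <- tchr
        lociS$tpos[r] <- sample(cand, 1L) + 4L  # offset off the slot grid
      }
    }

    present <- rep(TRUE, nrow(ancDf))
    lesion <- rep("none", nrow(ancDf))
    if (nrow(lociS)) {
      for (r in which(lociS$status == "deleted"))
        present[!is.na(ancDf$locus) & ancDf$locus == lociS$locus[r]] <- FALSE
    }

    # pseudogenizing lesions (conversion lineage kept intact)
    rIdx <- which(ancDf$role == "r_gene" & present &
                    (is.na(convLineage) | ancDf$lineage != convLineage))
    for (i in rIdx) {
      if (stats::runif(1) < config@pPseudogene) {
        type <- sample(names(config@lesionMix), 1L,
                       prob = config@lesionMix)
        ncod <- nchar(cds[i]) %/% 3L
        at <- sample(seq.int(max(2L, round(0.2 * ncod)),
                             max(3L, round(0.8 * ncod))), 1L)
        cds[i] <- applyLesion(cds[i], type, at,
                              cut = stats::runif(1, 0.3, 0.6))
        lesion[i] <- type
      }
    }

    # RLK family size co-varies with the retained R complement
    nAncR <- sum(ancDf$role == "r_gene")
    fRetained <- if (nAncR) sum(present[ancDf$role == "r_gene"]) / nAncR
                 else 1
    rlkTarget <- max(2L, round(config@rlkFamilyCount * fRetained))
    rlkIdx <- which(ancDf$role == "rlk")
    drop <- length(rlkIdx) - rlkTarget
    if (drop > 0L) present[sample(rlkIdx, drop)] <- FALSE

    # species gene order: ancestral order with deletions applied and
    # translocated loci re-inserted at their target position
    ord <- ancDf
    ord$ochr <- ord$chr; ord$opos <- ord$pos
    if (nrow(lociS)) {
      for (r in which(lociS$status == "translocated")) {
        at <- !is.na(ord$locus) & ord$locus == lociS$locus[r]
        ord$ochr[at] <- lociS$tchr[r]
        ord$opos[at] <- lociS$tpos[r]
      }
    }
    keep <- which(present)
    ord <- ord[keep, , drop = FALSE]
    o <- order(ord$ochr, ord$opos, ord$sub, ord$id)
    ord <- ord[o, , drop = FALSE]
    spCds <- cds[ord$id]

    geneIds <- sprintf("%s_g%04d", sp, seq_len(nrow(ord)))
    names(spCds) <- geneIds
    geneIdMap[[sp]] <- stats::setNames(geneIds, ord$id)

    widths <- nchar(spCds)
    startV <- integer(nrow(ord)); endV <- integer(nrow(ord))
    cur <- stats::setNames(rep(0L, nChr), as.character(seq_len(nChr)))
    for (i in seq_len(nrow(ord))) {
      chr <- as.character(ord$ochr[i])
      startV[i] <- cur[chr] + .GENE_SPACER + 1L
      endV[i] <- startV[i] + widths[i] - 1L
      cur[chr] <- endV[i]
    }
    tab <- data.frame(
      gene_id = geneIds,
      chromosome = sprintf("chr%d", ord$ochr),
      start = startV, end = endV,
      strand = "+",
      stringsAsFactors = FALSE)
    prots <- .translateMany(spCds)
    genomes[[s]] <- genomeAnnotation(
      sp, tab, Biostrings::DNAStringSet(spCds),
      Biostrings::AAStringSet(prots))

    truthGenesL[[s]] <- data.frame(
      species = sp, gene_id = geneIds, ancestral_id = ord$id,
      role = ord$role,
      lineage = ifelse(is.na(ord$lineage), NA_character_,
                       sprintf("lineage%02d", ord$lineage)),
      locus = ord$locus,
      intact = lesion[keep][o] == "none",
      lesion = lesion[keep][o],
      stringsAsFactors = FALSE)
    if (nrow(lociS))
      truthLociL[[s]] <- data.frame(
        locus = lociS$locus,
        lineage = sprintf("lineage%02d", lociS$lineage),
        species = sp, status = lociS$status,
        anc_chromosome = sprintf("chr%d", lociS$chr),
        stringsAsFactors = FALSE)
  }

  # --- plant conversion tracts ----------------------------------------------
  if (!is.na(convLineage) && config@nConversionTracts > 0L) {
    tg <- do.call(rbind, truthGenesL)
    conv <- tg[!is.na(tg$lineage) &
                 tg$lineage == sprintf("lineage%02d", convLineage) &
                 tg$intact, , drop = FALSE]
    bySp <- split(conv, conv$species)
    bySp <- bySp[vapply(bySp, nrow, integer(1)) >= 2L]
    if (length(bySp)) {
      for (t in seq_len(config@nConversionTracts)) {
        spTab <- bySp[[((t - 1L) %% length(bySp)) + 1L]]
        pair <- spTab[sample.int(nrow(spTab), 2L), ]
        sIdx <- match(pair$species[1], speciesNames)
        g <- genomes[[sIdx]]
        acc <- as.character(cdsSeqs(g)[[pair$gene_id[1]]])
        don <- as.character(cdsSeqs(g)[[pair$gene_id[2]]])
        len <- nchar(acc)
        # in-frame tract so the chimera stays an open reading frame
        tlen <- round(stats::runif(1, config@tractRange[1],
                                   min(config@tractRange[2], len - 9)))
        tlen <- max(3L, 3L * (tlen %/% 3L))
        maxStartCodon <- (len - tlen) %/% 3L - 1L
        at <- 3L * sample.int(max(1L, maxStartCodon), 1L) + 1L
        newCds <- plantConversion(acc, don, at, at + tlen - 1L)
        cdsSet <- cdsSeqs(g)
        cdsSet[[pair$gene_id[1]]] <- Biostrings::DNAString(newCds)
        protSet <- proteinSeqs(g)
        protSet[[pair$gene_id[1]]] <-
          Biostrings::AAString(.translateCds(newCds))
        genomes[[sIdx]] <- new("GenomeAnnotation", species = g@species,
                               genes = g@genes, cds = cdsSet,
                               proteins = protSet)
        convRows[[length(convRows) + 1L]] <- data.frame(
          species = pair$species[1], acceptor = pair$gene_id[1],
          donor = pair$gene_id[2], start = at, end = at + tlen - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }

  # --- ortholog truth ---------------------------------------------------------
  orthoL <- list()
  if (nSp >= 2L) {
    for (a in seq_len(nSp - 1L)) for (b in (a + 1L):nSp) {
      ma <- geneIdMap[[speciesNames[a]]]
      mb <- geneIdMap[[speciesNames[b]]]
      shared <- intersect(names(ma), names(mb))
      if (length(shared))
        orthoL[[length(orthoL) + 1L]] <- data.frame(
          species_a = speciesNames[a], gene_a = unname(ma[shared]),
          species_b = speciesNames[b], gene_b = unname(mb[shared]),
          ancestral_id = shared, stringsAsFactors = FALSE)
    }
  }
  emptyOrtho <- data.frame(species_a = character(), gene_a = character(),
                           species_b = character(), gene_b = character(),
                           ancestral_id = character())
  emptyConv <- data.frame(species = character(), acceptor = character(),
                          donor = character(), start = integer(),
                          end = integer())
  truth <- new("SimulatedTruth",
    genes = do.call(rbind, truthGenesL),
    loci = if (length(truthLociL)) do.call(rbind, truthLociL)
           else data.frame(locus = character(), lineage = character(),
                           species = character(), status = character(),
                           anc_chromosome = character()),
    orthologs = if (length(orthoL)) do.call(rbind, orthoL) else emptyOrtho,
    conversions = if (length(convRows)) do.call(rbind, convRows)
                  else emptyConv,
    config = config)
  list(genomes = stats::setNames(genomes, speciesNames), truth = truth)
}

#' Write a simulation to disk
#'
#' One directory per species (`genome.gff3`, `proteins.faa`, `cds.fna`),
#' the truth tables as TSV, and the configuration echoed as a key-value
#' text file.
#'
#' @param sim result of [simulateGenomes()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes)
    writeGenome(g, file.path(dir, species(g)))
  writeTable(truthGenes(sim$truth), file.path(dir, "truth_genes.tsv"))
  writeTable(truthLoci(sim$truth), file.path(dir, "truth_loci.tsv"))
  writeTable(truthOrthologs(sim$truth),
             file.path(dir, "truth_orthologs.tsv"))
  writeTable(truthConversions(sim$truth),
             file.path(dir, "truth_conversions.tsv"))
  cfg <- sim$truth@config
  slots <- slotNames(cfg)
  vals <- vapply(slots, function(s)
    paste(format(slot(cfg, s), digits = 12), collapse = ","), character(1))
  writeLines(paste0(slots, "=", vals), file.path(dir, "config.txt"))
  invisible(dir)
}
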