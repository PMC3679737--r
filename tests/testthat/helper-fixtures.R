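# Shared fixtures: tiny genomes and sequence helpers built in code.

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# a CDS (ATG + codons + TAA) encoding the given residues with random
# synonymous codons
codingFor <- function(aa) {
  tab <- split(names(Biostrings::GENETIC_CODE),
               unname(Biostrings::GENETIC_CODE))
  codons <- vapply(strsplit(aa, "")[[1]], function(r)
    sample(tab[[r]], 1L), character(1))
  paste(c("ATG", codons, "TAA"), collapse = "")
}

# mutate a fraction of positions (substitutions only)
mutateSeq <- function(s, frac) {
  chars <- strsplit(s, "")[[1]]
  idx <- sample(length(chars), round(frac * length(chars)))
  bases <- c("A", "C", "G", "T")
  chars[idx] <- vapply(chars[idx], function(b)
    sample(setdiff(bases, b), 1L), character(1))
  paste(chars, collapse = "")
}

# 3-gene toy genome with attached sequences
toyGenome <- function(species = "toy") {
  set.seed(401)
  cds <- Biostrings::DNAStringSet(c(g1 = codingFor("MKLV"),
                                    g2 = codingFor("HQRS"),
                                    g3 = codingFor("WYED")))
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    chromosome = "chr1",
                    start = c(100, 1000, 2000),
                    end = c(100, 1000, 2000) + Biostrings::width(cds) - 1,
                    strand = c("+", "-", "+"))
  genomeAnnotation(species, tab, cds)
}

# small simulation shared by several test files (cached per session)
.sharedSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateGenomes(simulationConfig(
        nSpecies = 2L, nChromosomes = 3L, genesPerChromosome = 50L,
        nRLineages = 4L, lineageSizeMean = 3, pLineageLoss = 0,
        pLocusDeletion = 0, pTranslocation = 0, pPseudogene = 0.4,
        rlkFamilyCount = 4L, seed = 11L))
    cache
  }
})

# two genomes where flank best hits are fully controllable: query has a
# focal gene X with 10 flanks per side; target holds orthologs of `inWin`
# flanks consecutively on chr1 and the rest far away on chr2
syntenyFixture <- function(inWin) {
  set.seed(61)
  n <- 21L
  qIds <- c(sprintf("L%02d", 1:10), "X", sprintf("R%02d", 1:10))
  qcds <- Biostrings::DNAStringSet(stats::setNames(
    replicate(n, codingFor("MKLVHQ")), qIds))
  qtab <- data.frame(gene_id = qIds, chromosome = "chr1",
                     start = seq_len(n) * 1000,
                     end = seq_len(n) * 1000 + Biostrings::width(qcds) - 1,
                     strand = "+")
  qg <- genomeAnnotation("qry", qtab, qcds)
  flanks <- setdiff(qIds, "X")
  tIds <- paste0("t_", flanks)
  tcds <- Biostrings::DNAStringSet(stats::setNames(
    replicate(20, codingFor("MKLVHQ")), tIds))
  near <- tIds[seq_len(inWin)]
  far <- setdiff(tIds, near)
  ttab <- data.frame(
    gene_id = c(near, far),
    chromosome = rep(c("chr1", "chr2"), c(length(near), length(far))),
    start = c(seq_along(near), seq_along(far)) * 1000,
    strand = "+")
  ttab$end <- ttab$start + Biostrings::width(tcds[ttab$gene_id]) - 1
  tg <- genomeAnnotation("tgt", ttab, tcds[ttab$gene_id])
  hits <- data.frame(query = flanks, subject = paste0("t_", flanks),
                     hsp_length = 600, identity = 95, score = 500)
  list(q = qg, t = tg, hits = hits)
}
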