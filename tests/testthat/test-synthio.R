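test_that("with all event probabilities zero, species are identical and truth is empty", {
  cfg <- simulationConfig(nSpecies = 3L, nChromosomes = 3L,
                          genesPerChromosome = 50L, nRLineages = 3L,
                          lineageSizeMean = 2, substitutionRate = 0,
                          pLineageLoss = 0, pLocusDeletion = 0,
                          pTranslocation = 0, pPseudogene = 0,
                          conversionLineage = FALSE, rlkFamilyCount = 3L,
                          seed = 5L)
  sim <- simulateGenomes(cfg)
  tabs <- lapply(sim$genomes, geneTable)
  # identical gene order and identical sequences across species
  for (s in 2:3) {
    expect_identical(tabs[[s]][, -1], tabs[[1]][, -1])
    expect_identical(unname(as.character(cdsSeqs(sim$genomes[[s]]))),
                     unname(as.character(cdsSeqs(sim$genomes[[1]]))))
  }
  tg <- truthGenes(sim$truth)
  expect_true(all(tg$intact))
  expect_true(all(truthLoci(sim$truth)$status == "retained"))
  expect_identical(nrow(truthConversions(sim$truth)), 0L)
})

test_that("certain lineage loss removes every lineage gene and marks loci deleted", {
  cfg <- simulationConfig(nSpecies = 2L, nChromosomes = 3L,
                          genesPerChromosome = 50L, nRLineages = 3L,
                          lineageSizeMean = 2, pLineageLoss = 1,
                          conversionLineage = FALSE, rlkFamilyCount = 2L,
                          seed = 6L)
  sim <- simulateGenomes(cfg)
  tg <- truthGenes(sim$truth)
  expect_identical(sum(tg$role == "r_gene"), 0L)
  expect_true(all(truthLoci(sim$truth)$status == "deleted"))
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- simulationConfig(nSpecies = 2L, nChromosomes = 2L,
                          genesPerChromosome = 40L, nRLineages = 2L,
                          lineageSizeMean = 2, rlkFamilyCount = 2L,
                          seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateGenomes(cfg), d1)
  writeSimulation(simulateGenomes(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(pLineageLoss = 1.2), "probabilities")
  expect_error(simulationConfig(
    lesionMix = c(frameshift = 0.5, nonsense = 0.5, partial = 0.5)),
    "sum to 1")
  expect_error(simulationConfig(genesPerChromosome = 0), "empty genome")
  expect_error(simulationConfig(tractRange = c(0, 10)), "tractRange")
})

test_that("plantConversion copies the donor tract and nothing else", {
  acc <- strrep("A", 40)
  don <- strrep("C", 40)
  expect_identical(plantConversion(acc, acc, 5, 10), acc)
  out <- plantConversion(acc, don, 10, 19)  # tract [10,20)
  chars <- strsplit(out, "")[[1]]
  expect_true(all(chars[10:19] == "C"))
  expect_true(all(chars[-(10:19)] == "A"))
  expect_error(plantConversion(acc, don, 35, 45), "bounds")
})

test_that("lesions edit the CDS as specified", {
  set.seed(7)
  cds <- paste0("ATG", strrep("GCT", 9), "TAA")
  out <- applyLesion(cds, "nonsense", 5)
  expect_true(substr(out, 13, 15) %in% c("TAA", "TAG", "TGA"))
  expect_identical(nchar(out), nchar(cds))

  # frameshift shortens the translated ORF
  orfLen <- function(x) {
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(x, 1, (nchar(x) %/% 3) * 3)),
      if.fuzzy.codon = "X")))
    stop1 <- regexpr("*", aa, fixed = TRUE)
    if (stop1 < 0) nchar(aa) else stop1 - 1
  }
  base <- codingFor(paste(rep("MKLVHQRSWYEDAKLVHQRS", 15), collapse = ""))
  fs <- applyLesion(base, "frameshift", 5)
  expect_true(abs(nchar(fs) - nchar(base)) %in% 1:2)
  expect_lt(orfLen(fs), orfLen(base))

  # partial truncation arithmetic
  p <- applyLesion(cds, "partial", 2, cut = 0.5)
  expect_identical(nchar(p), as.integer(ceiling(0.5 * nchar(cds))))
  expect_error(applyLesion(cds, "nonsense", 99), "beyond")
  expect_error(applyLesion(cds, "partial", 2, cut = 0.1), "30%")
})

test_that("planted conversion tracts lie within the acceptor and labels are unique", {
  sim <- .sharedSim()
  tg <- truthGenes(sim$truth)
  expect_false(any(duplicated(tg[, c("species", "gene_id")])))
  tc <- truthConversions(sim$truth)
  for (r in seq_len(nrow(tc))) {
    g <- sim$genomes[[tc$species[r]]]
    expect_lte(tc$end[r], Biostrings::width(cdsSeqs(g)[tc$acceptor[r]]))
    expect_gte(tc$start[r], 1L)
  }
  # ortholog truth is symmetric by construction: stored once per pair
  to <- truthOrthologs(sim$truth)
  expect_true(all(to$species_a < to$species_b))
})
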