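test_that("bestHits finds identical sequences with 100% identity and breaks ties deterministically", {
  set.seed(53)
  s1 <- randomDna(800); s2 <- randomDna(800)
  q <- Biostrings::DNAStringSet(c(q1 = s1))
  subj <- Biostrings::DNAStringSet(c(sB = s2, sZ = s1, sA = s1))
  h <- bestHits(q, subj)
  expect_identical(h$subject, "sA")  # equal score: lexicographic winner
  expect_equal(h$identity, 100)
  # query with no shared words is absent from the map
  q2 <- Biostrings::DNAStringSet(c(q1 = s1, lost = randomDna(800)))
  h2 <- bestHits(q2, subj)
  expect_false("lost" %in% h2$query)
})

test_that("ortholog calling enforces mutuality and the HSP/identity thresholds", {
  mk <- function(query, subject, hsp, idy)
    data.frame(query = query, subject = subject, hsp_length = hsp,
               identity = idy, score = hsp * idy / 100)
  ab <- mk("a1", "b1", 600, 85)
  ba <- mk("b1", "a1", 600, 85)
  expect_identical(nrow(callOrthologs(ab, ba)), 1L)
  # HSP boundary: "more than 500 bp" (501 passes, 499 and 500 do not)
  expect_identical(nrow(callOrthologs(mk("a1","b1",501,85),
                                      mk("b1","a1",501,85))), 1L)
  expect_identical(nrow(callOrthologs(mk("a1","b1",499,85),
                                      mk("b1","a1",499,85))), 0L)
  expect_identical(nrow(callOrthologs(mk("a1","b1",500,85),
                                      mk("b1","a1",500,85))), 0L)
  # identity boundary: "greater than 80%"
  expect_identical(nrow(callOrthologs(mk("a1","b1",600,81),
                                      mk("b1","a1",600,81))), 1L)
  expect_identical(nrow(callOrthologs(mk("a1","b1",600,79),
                                      mk("b1","a1",600,79))), 0L)
  # one-directional best is rejected
  expect_identical(nrow(callOrthologs(mk("a1","b1",600,85),
                                      mk("b1","a9",600,85))), 0L)
})

test_that("synteny windows require 14 of 20 co-windowed flank hits", {
  fx14 <- syntenyFixture(14L)
  syn <- syntenyWindow("X", fx14$q, fx14$t, fx14$hits)
  expect_false(is.null(syn))
  expect_identical(syn$chromosome, "chr1")
  expect_identical(syn$n_hits, 14L)
  fx13 <- syntenyFixture(13L)
  expect_null(syntenyWindow("X", fx13$q, fx13$t, fx13$hits))
})

test_that("PA status distinguishes present, translocated, deleted and gaps", {
  fx <- syntenyFixture(20L)
  syn <- syntenyWindow("X", fx$q, fx$t, fx$hits)
  orth <- data.frame(gene_a = "X", gene_b = "t_L05")  # inside the window
  expect_identical(
    callPaStatus("loc1", "X", orth, syn, fx$t)$status, "present")
  orthOut <- data.frame(gene_a = "X", gene_b = "t_L01")
  # move t_L01 out of the window by pretending the window excluded chr1
  synFar <- syn; synFar$chromosome <- "chr9"
  expect_identical(
    callPaStatus("loc1", "X", orthOut, synFar, fx$t)$status,
    "translocated")
  noOrth <- data.frame(gene_a = character(), gene_b = character())
  expect_identical(
    callPaStatus("loc1", "X", noOrth, syn, fx$t)$status,
    "absent-deleted")
  expect_identical(
    callPaStatus("loc1", "X", orth, NULL, fx$t)$status,
    "gap/unassessable")
})

test_that("planted deletions and translocations round-trip through PA calls", {
  sim <- simulateGenomes(simulationConfig(
    nSpecies = 2L, nChromosomes = 3L, genesPerChromosome = 50L,
    nRLineages = 5L, lineageSizeMean = 2, pLineageLoss = 0.3,
    pLocusDeletion = 0.2, pTranslocation = 0.2, pPseudogene = 0,
    conversionLineage = FALSE, rlkFamilyCount = 3L, seed = 83L))
  run <- list(genomes = sim$genomes, truth = sim$truth)
  run$candidates <- lapply(sim$genomes, function(g)
    findHomologs(identifyCandidates(g), g))
  tg <- truthGenes(sim$truth)
  tl <- truthLoci(sim$truth)
  expect_true(any(tl$status == "deleted"))
  cfg <- pipelineConfig(simulation = sim$truth@config,
                        stages = c("identify", "loci", "compare"))
  full <- runPipeline(cfg)
  ev <- evaluateAgainstTruth(full)
  expect_gte(ev$pa_accuracy, 0.95)
  # the deleted and translocated loci specifically are called as such
  pa <- full$pa_calls
  lmap <- do.call(rbind, lapply(names(full$loci), function(sp) {
    l <- full$loci[[sp]]
    l$anc <- tg$locus[match(paste(sp, l$gene_id),
                            paste(tg$species, tg$gene_id))]
    l
  }))
  key <- unique(lmap[, c("locus", "anc")])
  pa$anc <- key$anc[match(pa$locus, key$locus)]
  del <- tl[tl$status == "deleted", ]
  hits <- pa[paste(pa$anc, pa$target) %in% paste(del$locus, del$species), ]
  expect_gte(mean(hits$status == "absent-deleted"), 0.9)
})

test_that("a null simulation yields an all-present integrated map", {
  sim <- simulateGenomes(simulationConfig(
    nSpecies = 2L, nChromosomes = 2L, genesPerChromosome = 50L,
    nRLineages = 3L, lineageSizeMean = 2, pLineageLoss = 0,
    pLocusDeletion = 0, pTranslocation = 0, pPseudogene = 0,
    conversionLineage = FALSE, rlkFamilyCount = 2L, seed = 59L))
  run <- runPipeline(pipelineConfig(simulation = sim$truth@config,
                                    stages = c("identify", "models",
                                               "loci", "compare")))
  expect_true(all(run$pa_calls$status == "present"))
  expect_identical(sum(run$pseudogenes$verdict == "pseudogene"), 0L)
  statusCols <- grep("^status_", names(run$map), value = TRUE)
  for (sc in statusCols)
    expect_true(all(run$map[[sc]] == "present"))
  # shared-locus count equals the total locus count
  expect_identical(nrow(run$map),
                   length(unique(run$loci[[1]]$locus)))
})
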