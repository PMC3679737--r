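test_that("the shipped reference panel holds 18 clade models", {
  models <- readGeneModels()
  expect_length(models, 18L)
  expect_length(exonLengths(models[["T1-B"]]), 5L)
  expect_length(exonLengths(models[["T1-A"]]), 4L)
  expect_length(exonLengths(models[["T1-C"]]), 6L)
  # the three T1 variants share their first four exons
  expect_identical(exonLengths(models[["T1-C"]])[1:4],
                   exonLengths(models[["T1-B"]])[1:4])
  expect_identical(exonLengths(models[["T1-A"]]),
                   exonLengths(models[["T1-B"]])[1:4])
  # every model validates: one phase per internal junction, phases in 0:2
  for (m in models) expect_true(validObject(m))
})

test_that("inferGeneModel takes the majority structure and flags disagreement", {
  m4 <- list(exonLengths = c(100, 200, 150, 80), intronPhases = c(0, 1, 2))
  same <- inferGeneModel(list(m4, m4, m4))
  expect_false(same$disagreement)
  expect_identical(exonLengths(same$model), m4$exonLengths)
  expect_identical(intronPhases(same$model), m4$intronPhases)

  m5 <- list(exonLengths = c(100, 200, 150, 80, 60),
             intronPhases = c(0, 1, 2, 0))
  mixed <- inferGeneModel(list(m5, m5, m4))
  expect_true(mixed$disagreement)
  expect_length(exonLengths(mixed$model), 5L)

  single <- inferGeneModel(list(m4))
  expect_identical(exonLengths(single$model), m4$exonLengths)
  expect_error(inferGeneModel(list()), "no intact")
})

test_that("callPseudogene classifies planted lesions against a clade reference", {
  set.seed(23)
  ref <- codingFor(paste(sample(setdiff(LETTERS, c("B","J","O","U","X","Z")),
                                300, TRUE), collapse = ""))
  model <- geneModel("cl", nchar(ref) / 3, refCds = ref)

  expect_identical(callPseudogene("self", ref, model)$verdict, "intact")
  diverged <- mutateSeq(ref, 0.05)
  expect_identical(callPseudogene("div", diverged, model)$verdict, "intact")

  nonsense <- applyLesion(diverged, "nonsense", 120)
  callN <- callPseudogene("n", nonsense, model)
  expect_identical(callN$verdict, "pseudogene")
  expect_match(callN$lesions, "nonsense")

  fs <- applyLesion(diverged, "frameshift", 120)
  callF <- callPseudogene("f", fs, model)
  expect_identical(callF$verdict, "pseudogene")
  expect_match(callF$lesions, "frameshift")

  part <- applyLesion(diverged, "partial", 2, cut = 0.5)
  callP <- callPseudogene("p", part, model)
  expect_identical(callP$verdict, "pseudogene")
  expect_match(callP$lesions, "partial")

  noRef <- geneModel("cl", 300)
  expect_identical(callPseudogene("x", diverged, noRef)$verdict,
                   "unassessable")
})

test_that("pipeline pseudogene calls round-trip the planted lesions", {
  sim <- .sharedSim()
  tg <- truthGenes(sim$truth)
  # pooled subfamilies across the two genomes
  rIdsBySp <- lapply(names(sim$genomes), function(sp) {
    cand <- findHomologs(identifyCandidates(sim$genomes[[sp]]),
                         sim$genomes[[sp]])
    cand
  })
  names(rIdsBySp) <- names(sim$genomes)
  pooled <- do.call(c, unname(lapply(names(sim$genomes), function(sp) {
    ids <- rIdsBySp[[sp]]$gene_id[rIdsBySp[[sp]]$class %in%
                                    c("TIR", "non-TIR")]
    cdsSeqs(sim$genomes[[sp]])[ids]
  })))
  sf <- assignSubfamilies(pooled)
  motifIds <- unlist(lapply(rIdsBySp, function(cand)
    cand$gene_id[cand$class %in% c("TIR", "non-TIR") &
                   cand$evidence == "motif"]), use.names = FALSE)
  for (sp in names(sim$genomes)) {
    calls <- callPseudogenes(sim$genomes[[sp]], rIdsBySp[[sp]],
                             subfamilies = sf, ref_cds = pooled,
                             ref_motif_ids = motifIds)
    t1 <- tg[tg$species == sp, ]
    planted <- !t1$intact[match(calls$gene_id, t1$gene_id)]
    called <- calls$verdict == "pseudogene"
    expect_gte(mean(called[planted]), 0.95)
    expect_gte(mean(!called[!planted]), 0.95)
    # planted lesion types are among the reported lesions
    lesion <- t1$lesion[match(calls$gene_id, t1$gene_id)]
    for (type in c("nonsense", "frameshift", "partial")) {
      idx <- which(lesion == type & calls$verdict == "pseudogene")
      if (length(idx))
        expect_true(all(grepl(type, calls$lesions[idx])),
                    info = paste(sp, type))
    }
  }
})
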