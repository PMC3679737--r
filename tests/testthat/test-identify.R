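test_that("scanMotifs finds literal and class-degenerate motifs", {
  hits <- scanMotifs("MAAAGGVGKTTLLAA")
  ploop <- hits[hits$motif == "P-loop", ]
  expect_identical(ploop$position, 5L)
  expect_identical(ploop$score, 1)
  # GGMGKTT matches through the [VLMS] class position at full score
  hits2 <- scanMotifs("MAAAGGMGKTTLLAA")
  expect_identical(hits2$score[hits2$motif == "P-loop"], 1)
  # motif-free sequence
  expect_identical(nrow(scanMotifs(strrep("A", 60))), 0L)
  # one mismatch tolerated, scored below 1
  hits3 <- scanMotifs("MAAAGGVGKTALLAA")
  expect_identical(hits3$position[hits3$motif == "P-loop"], 5L)
  expect_equal(hits3$score[hits3$motif == "P-loop"], 6 / 7)
  expect_error(scanMotifs(""), "empty")
})

test_that("classifyCandidate applies the motif-chain rules", {
  pad <- function(n) strrep("A", n)
  nbs <- paste0("GGVGKTT", pad(40), "VLDDVW", pad(40), "CKGLPL")
  lrr <- strrep(paste0("LAD", "LRG", "LDL", "SGN"), 3)  # L..L..L.L..N x3
  tir <- paste0(pad(5), "FLSFRG", pad(10))
  expect_identical(
    classifyCandidate("g", scanMotifs(paste0(tir, nbs)))$class, "TIR")
  expect_identical(
    classifyCandidate("g", scanMotifs(paste0(pad(20), nbs)))$class,
    "non-TIR")
  cc <- classifyCandidate("g", scanMotifs(paste0(pad(20), nbs)))
  expect_identical(cc$nbs_start, 21L)
  expect_identical(cc$nbs_end, 21L + 7L + 40L + 6L + 40L + 6L - 1L)
  # kinase + >= 3 LRR repeats and no NBS chain -> LRR-RLK
  rlk <- paste0(pad(10), lrr, pad(10), "HRDLKSSN", pad(10))
  expect_identical(classifyCandidate("g", scanMotifs(rlk))$class,
                   "LRR-RLK")
  # out-of-order chain is rejected
  bad <- paste0(pad(10), "CKGLPL", pad(40), "VLDDVW", pad(40), "GGVGKTT")
  expect_identical(classifyCandidate("g", scanMotifs(bad))$class,
                   "rejected")
  expect_identical(classifyCandidate("g", scanMotifs(pad(80)))$class,
                   "rejected")
})

test_that("classification on simulated genomes has full sensitivity and no false positives", {
  sim <- .sharedSim()
  tg <- truthGenes(sim$truth)
  for (sp in names(sim$genomes)) {
    cand <- identifyCandidates(sim$genomes[[sp]])
    t1 <- tg[tg$species == sp, ]
    intact <- t1$gene_id[t1$role == "r_gene" & t1$intact]
    called <- cand$gene_id[cand$class %in% c("TIR", "non-TIR")]
    expect_identical(mean(intact %in% called), 1)
    expect_identical(
      mean(t1$gene_id[t1$role == "background"] %in% called), 0)
    expect_identical(
      sort(cand$gene_id[cand$class == "LRR-RLK"]),
      sort(t1$gene_id[t1$role == "rlk"]))
  }
})

test_that("findHomologs recruits lesioned relatives and reaches a fixed point", {
  sim <- .sharedSim()
  sp <- names(sim$genomes)[1]
  g <- sim$genomes[[sp]]
  cand <- identifyCandidates(g)
  rec1 <- findHomologs(cand, g)
  tg <- truthGenes(sim$truth)
  t1 <- tg[tg$species == sp, ]
  allR <- t1$gene_id[t1$role == "r_gene"]
  called <- rec1$gene_id[rec1$class %in% c("TIR", "non-TIR")]
  expect_true(all(allR %in% called))
  expect_true(all(rec1$evidence[rec1$gene_id %in%
    setdiff(allR, cand$gene_id[cand$class != "rejected"])] ==
      "homology-recruited"))
  # idempotence
  rec2 <- findHomologs(rec1, g)
  expect_identical(rec2$class, rec1$class)
  # a 50%-identity sequence is not recruited
  bait <- as.character(cdsSeqs(g)[[called[1]]])
  far <- mutateSeq(bait, 0.5)
  tab <- geneTable(g)[1, ]
  tab$gene_id <- "gFar"; tab$end <- tab$start + nchar(far) - 1
  g2 <- genomeAnnotation("t", rbind(geneTable(g)[, names(tab)], tab),
                         c(cdsSeqs(g), Biostrings::DNAStringSet(c(gFar = far))))
  cand2 <- rbind(rec1, data.frame(gene_id = "gFar", class = "rejected",
                                  nbs_start = NA_integer_,
                                  nbs_end = NA_integer_,
                                  evidence = NA_character_))
  rec3 <- findHomologs(cand2, g2)
  expect_identical(rec3$class[rec3$gene_id == "gFar"], "rejected")
})

test_that("in-silico PCR honours sites, orientation, product range and the 3' clamp", {
  set.seed(31)
  fwd <- "GGIGGIGTIGGIAARACIAC"
  rev <- "CCAIACRTCRTCNARNAC"
  ploopSite <- "GGTGGGGTTGGGAAGACAAC"   # matches 15914 with I -> N
  k2Site <- "GTGCTTGATGACGTTTGG"        # VLDDVW codons; rev primer site
  mid <- randomDna(262)
  template <- paste0(randomDna(50), ploopSite, mid, k2Site, randomDna(50))
  got <- insilicoPcr(template, fwd, rev)
  expect_identical(nrow(got), 1L)
  expect_identical(got$length, nchar(ploopSite) + 262L + nchar(k2Site))
  # out-of-range product (sites too far apart)
  template2 <- paste0(randomDna(50), ploopSite, randomDna(900), k2Site)
  expect_identical(nrow(insilicoPcr(template2, fwd, rev)), 0L)
  # a mismatch in the 3' clamp kills the site
  brokenClamp <- paste0(substr(ploopSite, 1, 17), "GGG")
  template3 <- paste0(randomDna(50), brokenClamp, mid, k2Site)
  expect_identical(nrow(insilicoPcr(template3, fwd, rev)), 0L)
  # two mismatches outside the clamp are tolerated
  loose <- paste0("TT", substr(ploopSite, 3, 20))
  template4 <- paste0(randomDna(50), loose, mid, k2Site)
  expect_identical(nrow(insilicoPcr(template4, fwd, rev)), 1L)
  expect_error(insilicoPcr(template, "GGIGG", rev), "15")
})

test_that("fragment deduplication applies the 99.5% single-linkage rule", {
  set.seed(17)
  base <- randomDna(1000)
  at996 <- mutateSeq(base, 4 / 1000)
  at994 <- mutateSeq(base, 6 / 1000)
  d1 <- dedupFragments(c(a = base, b = at996))
  expect_identical(length(unique(d1$group)), 1L)
  d2 <- dedupFragments(c(a = base, b = at994))
  expect_identical(length(unique(d2$group)), 2L)
  d3 <- dedupFragments(c(a = base, b = base, c = base))
  expect_identical(length(unique(d3$group)), 1L)
  expect_identical(d3$id[d3$representative], "a")  # longest, then lexicographic
  # order invariance
  d4 <- dedupFragments(c(b = at996, a = base))
  expect_identical(length(unique(d4$group)), 1L)
})
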