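test_that("subfamily clustering respects the 70% identity threshold", {
  set.seed(101)
  base <- randomDna(1000)
  at72 <- mutateSeq(base, 0.28)
  at68 <- mutateSeq(base, 0.32)
  # the constructions really sit at the intended identities
  expect_gte(alignPair(base, at72, type = "local")$identity, 70)
  expect_lt(alignPair(base, at68, type = "local")$identity, 70)
  sf1 <- assignSubfamilies(c(a = base, b = at72))
  expect_identical(length(unique(sf1$subfamily)), 1L)
  sf2 <- assignSubfamilies(c(a = base, b = at68))
  expect_identical(length(unique(sf2$subfamily)), 2L)
  # order invariance
  sf3 <- assignSubfamilies(c(b = at72, a = base))
  expect_identical(sf3[order(sf3$gene_id), ]$subfamily,
                   sf1[order(sf1$gene_id), ]$subfamily)
})

test_that("simulated lineages come back as subfamilies exactly", {
  sim <- .sharedSim()
  tg <- truthGenes(sim$truth)
  pooled <- do.call(c, unname(lapply(names(sim$genomes), function(sp) {
    ids <- tg$gene_id[tg$species == sp & tg$role == "r_gene"]
    cdsSeqs(sim$genomes[[sp]])[ids]
  })))
  sf <- assignSubfamilies(pooled)
  lin <- tg$lineage[match(sf$gene_id, tg$gene_id)]
  tab <- table(sf$subfamily, lin)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("family summaries count classes and average per subfamily", {
  cand <- list(spA = data.frame(
    gene_id = sprintf("g%d", 1:12),
    class = c(rep("TIR", 4), rep("non-TIR", 6), "LRR-RLK", "rejected")),
    spB = data.frame(gene_id = character(), class = character()))
  sf <- list(spA = data.frame(gene_id = sprintf("g%d", 1:10),
                              subfamily = rep(c("SF01", "SF02"), 5)),
             spB = data.frame(gene_id = character(),
                              subfamily = character()))
  fs <- familySummary(cand, sf)
  a <- fs[fs$species == "spA", ]
  expect_identical(a$total, 10L)
  expect_identical(a$tir, 4L)
  expect_identical(a$non_tir, 6L)
  expect_identical(a$subfamilies, 2L)
  expect_identical(a$mean_per_subfamily, 5)
  b <- fs[fs$species == "spB", ]
  expect_identical(b$total, 0L)
  expect_identical(b$subfamilies, 0L)
  # a user-supplied reported mean rides alongside the computed one
  fs2 <- familySummary(cand, sf, reported_mean = c(spA = 5.0, spB = 0))
  expect_identical(fs2$reported_mean[fs2$species == "spA"], 5.0)
})

test_that("clade sharing statistics reproduce the published proportion", {
  cf <- data.frame(
    clade = c(sprintf("S%02d", 1:23), rep(sprintf("M%02d", 1:16), 2)),
    family = c(rep("Cucurbitaceae", 23),
               rep(c("Fabaceae", "Salicaceae"), each = 16)))
  st <- cladeSharingStats(cf)
  expect_identical(st$n_clades, 39L)
  expect_identical(st$n_shared, 16L)
  expect_identical(st$n_specific, 23L)
  expect_identical(st$percent_specific, 58.9)
  allShared <- data.frame(clade = rep(c("c1", "c2"), 2),
                          family = c("A", "A", "B", "B"))
  expect_identical(cladeSharingStats(allShared)$percent_specific, 0)
  one <- data.frame(clade = "c1", family = "A")
  expect_identical(cladeSharingStats(one)$percent_specific, 100)
})

test_that("pearsonR reproduces the published correlation and the closed form", {
  r <- pearsonR(c(70, 75, 55, 450, 552), c(189, 169, 184, 501, 447))
  expect_identical(round(r, 2), 0.96)
  expect_identical(pearsonR(c(1, 2, 3), c(2, 4, 6)), 1)
  # independent covariance/sd computation
  set.seed(107)
  x <- rnorm(20); y <- rnorm(20)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y), manual, tolerance = 1e-12)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  # affine invariance
  expect_equal(pearsonR(10 + 3 * x, y), pearsonR(x, y), tolerance = 1e-12)
})

test_that("the Welch t-test flags the family-size contrast", {
  same <- twoSampleT(c(3, 4, 5), c(3, 4, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  diff <- twoSampleT(c(5, 4, 3), c(15, 16, 15))
  expect_lt(diff$p, 0.05)
  # closed-form Welch check
  a <- c(5, 4, 3); b <- c(15, 16, 15)
  tManual <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  expect_equal(diff$t, tManual, tolerance = 1e-12)
  # within-group order invariance
  expect_identical(twoSampleT(c(3, 5, 4), c(16, 15, 15))$p, diff$p)
  expect_error(twoSampleT(1, c(1, 2)), "at least 2")
})
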