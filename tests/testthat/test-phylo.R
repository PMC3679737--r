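test_that("p-distance follows the gap-excluding definition", {
  expect_identical(pDistance("GGVGKTT", "GGVGKTT"), 0)
  expect_equal(pDistance("GGVGKTT", "GGMGKTT"), 1 / 7)
  expect_identical(pDistance("AB-D", "ABCD"), 0)  # 3 compared columns
  expect_error(pDistance("---", "ABC"), "no comparable")
  expect_error(pDistance("AB", "ABC"), "equal length")
})

test_that("K2P distance matches the closed form and saturates loudly", {
  a20 <- strrep("A", 20)
  b20 <- paste0("GGC", strrep("A", 17))  # 2 transitions, 1 transversion
  expect_identical(k2pDistance(a20, a20), 0)
  expect_equal(k2pDistance(a20, b20),
               -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)),
               tolerance = 1e-12)
  expect_lt(abs(k2pDistance(a20, b20) - 0.1702), 1e-4)
  bq <- paste0("C", strrep("A", 19))  # P = 0, Q = 0.05
  expect_equal(k2pDistance(a20, bq), -0.5 * log(0.95 * sqrt(0.90)),
               tolerance = 1e-12)
  expect_lt(abs(k2pDistance(a20, bq) - 0.0520), 1e-4)
  expect_error(k2pDistance("AAAA", "GGGG"), "saturated")
})

test_that("K2P dominates the nucleotide p-distance whenever both exist", {
  set.seed(13)
  for (i in 1:20) {
    a <- randomDna(300)
    b <- mutateSeq(a, runif(1, 0.01, 0.25))
    k <- tryCatch(k2pDistance(a, b), error = function(e) NA)
    if (!is.na(k)) expect_gte(k, pDistance(a, b))
  }
})

test_that("neighbor-joining recovers additive matrices exactly", {
  D <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- njTree(D)
  # AB|CD split with all terminal branches 1 and internal branch 1
  expect_identical(ape::Ntip(tr), 4L)
  splits <- ape::prop.part(tr)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[
    rownames(D), colnames(D)]), unname(D), tolerance = 1e-12)
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 1, 1), tolerance = 1e-12)

  # tree -> additive matrix -> NJ inverts exactly on random trees
  set.seed(19)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    sim <- ape::rtree(n, rooted = FALSE)
    Dm <- ape::cophenetic.phylo(sim)
    rec <- njTree(Dm)
    expect_identical(ape::dist.topo(ape::unroot(sim), rec)[1], 0)
    expect_equal(as.matrix(ape::cophenetic.phylo(rec))[
      rownames(Dm), colnames(Dm)], Dm, tolerance = 1e-8)
  }

  # taxon order invariance
  perm <- c("C", "A", "D", "B")
  tr2 <- njTree(D[perm, perm])
  expect_identical(ape::dist.topo(tr, tr2)[1], 0)
  expect_error(njTree(D[1:2, 1:2]), "3 taxa")
})

test_that("bootstrap supports are deterministic and separate planted groups", {
  set.seed(29)
  anc1 <- randomDna(240); anc2 <- mutateSeq(anc1, 0.5)
  aln <- Biostrings::DNAStringSet(c(
    a1 = mutateSeq(anc1, 0.03), a2 = mutateSeq(anc1, 0.03),
    a3 = mutateSeq(anc1, 0.03),
    b1 = mutateSeq(anc2, 0.03), b2 = mutateSeq(anc2, 0.03),
    b3 = mutateSeq(anc2, 0.03)))
  tr <- bootstrapSupport(aln, B = 100L, type = "k2p", seed = 3L)
  D <- distanceMatrix(aln, type = "k2p", saturated = "cap")
  clades <- extractClades(tr, D, min_support = 80, distance_cutoff = 0.3)
  byClade <- split(clades$member, clades$clade)
  expect_identical(unname(sort(vapply(byClade, function(x)
    paste(sort(x), collapse = ","), character(1)), method = "radix")),
    sort(c("a1,a2,a3", "b1,b2,b3"), method = "radix"))
  expect_gte(min(clades$support, na.rm = TRUE), 95)
  # determinism under the seed
  tr2 <- bootstrapSupport(aln, B = 100L, type = "k2p", seed = 3L)
  expect_identical(tr2$node.label, tr$node.label)
  # B = 1 gives all-or-nothing supports
  tr1 <- bootstrapSupport(aln, B = 1L, type = "k2p", seed = 3L)
  expect_true(all(tr1$node.label %in% c(0L, 100L, NA_integer_)))
})

test_that("clade extraction respects support and distance rules and partitions taxa", {
  set.seed(37)
  anc <- randomDna(300)
  aln <- Biostrings::DNAStringSet(c(
    a1 = mutateSeq(anc, 0.02), a2 = mutateSeq(anc, 0.02),
    a3 = mutateSeq(anc, 0.02), a4 = mutateSeq(anc, 0.02),
    out = mutateSeq(anc, 0.45)))
  tr <- bootstrapSupport(aln, B = 100L, type = "p", seed = 5L)
  D <- distanceMatrix(aln, type = "p")
  cl <- extractClades(tr, D)
  # all taxa covered exactly once
  expect_identical(sort(cl$member), sort(names(aln)))
  expect_false(any(duplicated(cl$member)))
  # the distant taxon is a singleton
  expect_identical(sum(cl$member == "out"), 1L)
  expect_identical(sum(cl$clade == cl$clade[cl$member == "out"]), 1L)
  # one compact well-supported clade holds the rest
  expect_identical(length(unique(cl$clade[cl$member != "out"])), 1L)
  # with every taxon close on one perfect edge, a single clade emerges
  aln2 <- Biostrings::DNAStringSet(c(
    x1 = mutateSeq(anc, 0.01), x2 = mutateSeq(anc, 0.01),
    x3 = mutateSeq(anc, 0.01), x4 = mutateSeq(anc, 0.01)))
  tr2 <- bootstrapSupport(aln2, B = 100L, type = "p", seed = 5L)
  cl2 <- extractClades(tr2, distanceMatrix(aln2, type = "p"))
  expect_identical(length(unique(cl2$clade)), 1L)
})
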