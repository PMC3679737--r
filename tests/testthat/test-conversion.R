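test_that("polymorphic site detection matches a brute-force column scan", {
  aln <- c(a = "AAAA", b = "AAAA", c = "AAAA")
  expect_identical(as.integer(polymorphicSites(aln)), integer(0))
  aln2 <- c(a = "AATA", b = "AAAA", c = "AAAA")
  expect_identical(as.integer(polymorphicSites(aln2)), 3L)
  expect_error(polymorphicSites(c(a = "AA", b = "AA")), "3 sequences")
  set.seed(71)
  for (i in 1:5) {
    m <- matrix(sample(c("A", "C", "G", "T", "-"), 5 * 100, TRUE,
                       prob = c(rep(0.24, 4), 0.04)), 5, 100)
    rownames(m) <- paste0("s", 1:5)
    got <- as.integer(polymorphicSites(m, max_gap_frac = 0.2))
    oracle <- which(vapply(seq_len(100), function(j) {
      col <- m[, j]
      gaps <- col == "-"
      mean(gaps) <= 0.2 && length(unique(col[!gaps])) >= 2
    }, logical(1)))
    expect_identical(got, oracle)
  }
})

test_that("fragments are maximal zero-mismatch runs bounded by disagreements", {
  # 10 polymorphic sites; rows a and b agree exactly at sites 3..7
  base <- strsplit(strrep("A", 10), "")[[1]]
  a <- base; b <- base
  b[c(1, 2, 8, 9, 10)] <- "C"      # disagreements with a
  cseq <- rep("G", 10)             # third row makes every column polymorphic
  aln <- c(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
           c = paste(cseq, collapse = ""))
  sites <- polymorphicSites(aln)
  fr <- findFragments("a", "b", sites, aln)
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$n_sites, 5L)
  expect_identical(c(fr$first_site, fr$last_site), c(3L, 7L))
  # a pair disagreeing everywhere yields nothing
  frAC <- findFragments("a", "c", sites, aln)
  expect_identical(nrow(frAC), 0L)
  # a pair agreeing everywhere (run spans the whole profile) yields nothing
  aln2 <- c(a = aln[["a"]], b = aln[["a"]], c = aln[["c"]])
  names(aln2) <- c("a", "b", "c")
  fr2 <- findFragments("a", "b", polymorphicSites(aln2), aln2)
  expect_identical(nrow(fr2), 0L)
})

test_that("permutation p-values match exact enumeration on a tiny profile", {
  # 3 sequences, 6 polymorphic sites; enumerate all 720 permutations
  aln <- c(a = "ACACAC", b = "ACCAAC", c = "GTGTGT")
  sites <- polymorphicSites(aln)
  m <- attr(sites, "matrix")
  pos <- as.integer(sites)
  # observed fragment for (a, b): leading run of agreements
  fr <- findFragments("a", "b", sites, aln)
  s <- max(fr$n_sites)
  span <- fr$span_bp[which.max(fr$n_sites)]
  # independent oracle: collect agreement runs by explicit scan, drop
  # full-profile runs, take the best (sites, span) composite
  naiveBest <- function(x, y, posv) {
    agree <- x == y
    n <- length(agree)
    best <- c(0L, 0L)
    k <- 1L
    while (k <= n) {
      if (agree[k]) {
        j <- k
        while (j < n && agree[j + 1L]) j <- j + 1L
        len <- j - k + 1L
        spanR <- posv[j] - posv[k] + 1L
        if (len < n &&
            (len > best[1] || (len == best[1] && spanR > best[2])))
          best <- c(len, spanR)
        k <- j + 1L
      } else k <- k + 1L
    }
    best
  }
  allPerms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  allPerms <- allPerms[apply(allPerms, 1, function(p)
    length(unique(p)) == 6), , drop = FALSE]
  pairs <- utils::combn(3, 2)
  exceed <- apply(allPerms, 1, function(p) {
    best <- c(0L, 0L)
    for (k in seq_len(ncol(pairs))) {
      b <- naiveBest(m[pairs[1, k], sites][p], m[pairs[2, k], sites][p],
                     pos)
      if (b[1] > best[1] || (b[1] == best[1] && b[2] > best[2]))
        best <- b
    }
    best[1] > s || (best[1] == s && best[2] >= span)
  })
  exact <- mean(exceed)
  mc <- permutationPvalue(s, aln, span_bp = span, n_perm = 2000L,
                          seed = 3L)
  # Monte-Carlo estimate within a generous binomial envelope of the exact
  expect_lt(abs(mc - exact), 3 * sqrt(exact * (1 - exact) / 2000) + 1e-3)
  # a minimal score is never significant
  expect_gt(permutationPvalue(1, aln, n_perm = 200L, seed = 3L), 0.5)
})

test_that("planted tracts are detected and input order does not matter", {
  set.seed(89)
  anc <- randomDna(1200)
  seqs <- vapply(1:4, function(i) mutateSeq(anc, 0.05), character(1))
  # plant a 400 bp exchange: sequence 1 receives 501..900 from sequence 2
  seqs[1] <- plantConversion(seqs[1], seqs[2], 501, 900)
  aln <- Biostrings::DNAStringSet(stats::setNames(seqs, paste0("g", 1:4)))
  det <- detectConversions(aln, alpha = 0.05, n_perm = 500L, seed = 13L)
  expect_gt(nrow(det$events), 0L)
  hit <- det$events[(det$events$seq_i == "g1" & det$events$seq_j == "g2") |
                    (det$events$seq_i == "g2" & det$events$seq_j == "g1"), ]
  expect_gt(nrow(hit), 0L)
  overlap <- pmax(0, pmin(hit$last_site, 900) - pmax(hit$first_site, 501))
  expect_gte(max(overlap) / 400, 0.5)
  expect_true(all(det$events$p >= 0 & det$events$p <= 1))
  # order invariance
  det2 <- detectConversions(rev(aln), alpha = 0.05, n_perm = 500L,
                            seed = 13L)
  expect_identical(det2$events[, c("seq_i", "seq_j", "first_site",
                                   "last_site", "p")],
                   det$events[, c("seq_i", "seq_j", "first_site",
                                  "last_site", "p")])
  # painting groups both partners of each reported tract
  expect_true(all(c(hit$seq_i, hit$seq_j) %in% det$painting$sequence))
  # two sequences are not enough
  expect_error(detectConversions(aln[1:2]), "3 sequences")
})
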