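test_that("k-mer counting matches hand enumeration and its contracts", {
  g <- buildGraph("ACGTAC", 3)
  expect_identical(kmerCounts(g), oracleKmers("ACGTAC", 3))

  # read shorter than k contributes nothing
  expect_length(kmerCounts(buildGraph("ACGT", 7)), 0L)

  # additivity: same read twice doubles every multiplicity
  g1 <- buildGraph(c("ACGTACGGT"), 5)
  g2 <- buildGraph(c("ACGTACGGT", "ACGTACGGT"), 5)
  expect_identical(kmerCounts(g2), 2L * kmerCounts(g1))

  # k-mers containing N are skipped
  gn <- buildGraph("ACGNACG", 3)
  expect_identical(kmerCounts(gn), oracleKmers("ACGNACG", 3))

  # even k rejected
  expect_error(buildGraph("ACGTACGT", 4), "odd")

  # random agreement with the oracle
  set.seed(8)
  reads <- vapply(1:20, function(i) randomDNA(sample(10:40, 1)),
                  character(1))
  for (k in c(5, 9, 15))
    expect_identical(kmerCounts(buildGraph(reads, k)),
                     oracleKmers(reads, k))
})

test_that("graph cleaning removes error branches, tips and bubbles", {
  set.seed(14)
  genome <- randomDNA(500)
  reads <- vapply(seq(1, 400, by = 4), function(s)
    substr(genome, s, s + 99), character(1))
  # identity: nothing below threshold, no tips/bubbles
  g <- buildGraph(reads, 21)
  gc <- cleanGraph(g, minCoverage = 1, maxTipLength = 0)
  expect_identical(kmerCounts(gc), kmerCounts(g))

  # a single error in one read at high coverage: the multiplicity-1 branch
  # disappears at minCoverage 2
  bad <- reads[10]
  substr(bad, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, 50, 50))[1]
  gErr <- buildGraph(c(reads, bad), 21)
  gClean <- cleanGraph(gErr, minCoverage = 2, maxTipLength = 0)
  kc <- kmerCounts(gClean)
  expect_true(all(names(kc) %in% names(kmerCounts(g))))
  ct <- extractContigs(gClean)
  expect_length(ct, 1L)
  expect_true(isSubstringEitherStrand(as.character(ct[[1]]), genome))

  # a true bubble: two variants of the same region between shared flanks
  varA <- genome
  varB <- genome
  substr(varB, 250, 250) <- setdiff(c("A", "C", "G", "T"),
                                    substr(genome, 250, 250))[1]
  readsA <- vapply(seq(1, 400, by = 10), function(s)
    substr(varA, s, s + 99), character(1))
  readsB <- vapply(seq(1, 400, by = 10), function(s)
    substr(varB, s, s + 99), character(1))
  gBub <- buildGraph(c(readsA, readsB, readsA), 21) # A at higher coverage
  popped <- cleanGraph(gBub, minCoverage = 1, maxTipLength = 0)
  ctb <- extractContigs(popped)
  expect_length(ctb, 1L)
  expect_true(isSubstringEitherStrand(as.character(ctb[[1]]), varA))
})

test_that("unitig extraction spells maximal unbranched paths", {
  # one linear path (string free of repeated or palindromic 4-mers)
  g <- buildGraph("CTTCGGGTGACATTGC", 5)
  ct <- extractContigs(g)
  expect_length(ct, 1L)
  expect_identical(as.character(ct[[1]]), canonChr("CTTCGGGTGACATTGC"))

  # exact repeat of length >= k splits the assembly; every contig remains a
  # genome substring (either strand)
  set.seed(25)
  left <- randomDNA(200); mid <- randomDNA(200); right <- randomDNA(200)
  rep50 <- randomDNA(50)
  genome <- paste0(left, rep50, mid, rep50, right)
  reads <- vapply(seq(1, nchar(genome) - 119, by = 2), function(s)
    substr(genome, s, s + 119), character(1))
  ctRep <- extractContigs(buildGraph(reads, 31))
  expect_gt(length(ctRep), 1L)
  for (s in as.character(ctRep))
    expect_true(isSubstringEitherStrand(s, genome))

  # with k > repeat length the repeat is spanned: a single contig equal to
  # the genome
  ctSpan <- extractContigs(buildGraph(reads, 61))
  expect_length(ctSpan, 1L)
  expect_identical(as.character(ctSpan[[1]]), canonChr(genome))
})

test_that("edge conservation: contigs spell exactly the graph k-mers", {
  set.seed(31)
  reads <- vapply(1:40, function(i) randomDNA(60), character(1))
  for (k in c(15, 21)) {
    g <- buildGraph(reads, k)
    ct <- extractContigs(g)
    spelled <- oracleKmers(as.character(ct), k)
    expect_identical(names(spelled), names(kmerCounts(g)))
    expect_true(all(spelled == 1L))
  }
})

test_that("multi-k assembly runs one independent assembly per k", {
  tl <- tinyLibrary(seed = 33, genomeLength = 5000, coverage = 30)
  prep <- preprocessReads(tl$lib$forward, tl$lib$reverse, tl$cfg@adapter)
  asms <- suppressWarnings(
    multiKAssemble(prep$merged, kList = seq(37L, 127L, by = 10L)))
  expect_length(asms, 10L)
  expect_named(asms, paste0("k", seq(37, 127, by = 10)))

  # k = 37 on an error-free repeat-free genome at 30x: one contig = genome
  k37 <- asms$k37
  expect_length(k37, 1L)
  expect_identical(as.character(k37[[1]]),
                   canonChr(as.character(genomeSeq(tl$lib$genome))))
  expect_identical(S4Vectors::mcols(k37)$k, 37L)

  # a k larger than every read: empty assembly with a warning
  reads101 <- ReadSet(DNAStringSet(
    setNames(vapply(1:30, function(i) randomDNA(101), character(1)),
             paste0("r", 1:30))))
  expect_warning(a107 <- multiKAssemble(reads101, kList = 107L),
                 "no contigs")
  expect_length(a107$k107, 0L)
})

test_that("assembly is sound, deterministic and repeat-monotone", {
  set.seed(40)
  # soundness at zero error on a simulated library
  tl <- tinyLibrary(seed = 44, genomeLength = 4000, coverage = 25)
  gseq <- as.character(genomeSeq(tl$lib$genome))
  prep <- preprocessReads(tl$lib$forward, tl$lib$reverse, tl$cfg@adapter)
  asm <- multiKAssemble(prep$merged, kList = c(37L, 57L))
  for (ct in asm)
    for (s in as.character(ct))
      expect_true(isSubstringEitherStrand(s, gseq))

  # determinism: contig output independent of read input order
  reads <- prep$merged
  shuffled <- reads[sample(length(reads))]
  a1 <- extractContigs(cleanGraph(buildGraph(reads, 37)))
  a2 <- extractContigs(cleanGraph(buildGraph(shuffled, 37)))
  expect_identical(as.character(a1), as.character(a2))

  # monotone repeat behaviour: k above the planted repeat length produces
  # fewer contigs than k below it
  rep <- tinyLibrary(seed = 45, genomeLength = 6000, coverage = 30,
                     repeats = data.frame(unitLength = 40, copies = 3,
                                          divergence = 0))
  prepR <- preprocessReads(rep$lib$forward, rep$lib$reverse,
                           rep$cfg@adapter)
  nLow <- length(extractContigs(cleanGraph(buildGraph(prepR$merged, 31))))
  nHigh <- length(extractContigs(cleanGraph(buildGraph(prepR$merged, 61))))
  expect_gt(nLow, nHigh)
})
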