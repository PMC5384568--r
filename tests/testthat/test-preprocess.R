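ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

test_that("adapter clipping removes read-through and is idempotent", {
  frag <- "TGCATGCCATGGATCGATCC" # ends in C: no spurious adapter-like suffix
  read <- ReadSet(DNAStringSet(c(r1 = paste0(frag, ADAPTER),
                                 r2 = frag,
                                 r3 = paste0(frag, substr(ADAPTER, 1, 5)))),
                  mate = "SINGLE")
  out <- clipAdapter(read, ADAPTER, minOverlap = 3, maxMismatchFrac = 0)
  expect_identical(as.character(readSequences(out))[["r1"]], frag)
  # no admissible match: unchanged
  expect_identical(as.character(readSequences(out))[["r2"]], frag)
  # read ending in the first 5 adapter bases: those 5 removed
  expect_identical(as.character(readSequences(out))[["r3"]], frag)
  # idempotence
  out2 <- clipAdapter(out, ADAPTER, minOverlap = 3, maxMismatchFrac = 0)
  expect_identical(as.character(readSequences(out2)),
                   as.character(readSequences(out)))
})

test_that("adapter clipping agrees with a brute-force alignment scan", {
  # oracle: leftmost p whose suffix matches an adapter prefix (exact),
  # repeated to fixpoint
  oracleClip <- function(s, adapter, minOv) {
    repeat {
      n <- nchar(s); hit <- NA
      for (p in seq_len(n)) {
        L <- min(n - p + 1L, nchar(adapter))
        if (L < minOv) break
        if (substr(s, p, p + L - 1L) == substr(adapter, 1, L)) {
          hit <- p; break
        }
      }
      if (is.na(hit)) return(s)
      s <- substr(s, 1, hit - 1L)
    }
  }
  set.seed(42)
  reads <- vapply(1:60, function(i) {
    frag <- randomDNA(sample(20:60, 1))
    if (i %% 2) paste0(frag, substr(ADAPTER, 1, sample(1:33, 1))) else frag
  }, character(1))
  rs <- ReadSet(DNAStringSet(setNames(reads, paste0("r", seq_along(reads)))))
  got <- as.character(readSequences(
    clipAdapter(rs, ADAPTER, minOverlap = 3, maxMismatchFrac = 0)))
  want <- vapply(reads, oracleClip, character(1), adapter = ADAPTER,
                 minOv = 3, USE.NAMES = FALSE)
  expect_identical(unname(got), want)
})

test_that("quality trimming clips 3' ends and discards short reads", {
  qstr <- function(q) rawToChar(as.raw(q + 33L))
  rs <- ReadSet(DNAStringSet(c(a = "ACGT", b = "ACGT", c = "ACGT")),
                c(qstr(c(40, 40, 2, 2)), qstr(c(30, 30, 30, 30)),
                  qstr(c(2, 2, 2, 2))))
  out <- qualityTrim(rs, qThreshold = 20, minLength = 1)
  expect_identical(as.character(readSequences(out)),
                   c(a = "AC", b = "ACGT"))
  expect_length(qualityTrim(rs[3], qThreshold = 20, minLength = 1), 0L)
  # idempotence
  out2 <- qualityTrim(out, qThreshold = 20, minLength = 1)
  expect_identical(as.character(readSequences(out2)),
                   as.character(readSequences(out)))
})

test_that("pair merging reconstructs fragments and applies the consensus rule", {
  set.seed(7)
  frag <- randomDNA(150)
  fwd <- ReadSet(DNAStringSet(c(p = substr(frag, 1, 101))), mate = "FORWARD")
  rev <- ReadSet(DNAStringSet(c(p = rcChr(substr(frag, 50, 150)))),
                 mate = "REVERSE")
  mg <- mergePairs(fwd, rev, minOverlap = 10)
  expect_length(mg$merged, 1L)
  merged <- as.character(readSequences(mg$merged))[[1]]
  expect_identical(merged, frag)
  expect_equal(nchar(merged), 101 + 101 - 52) # len(fwd)+len(rev)-overlap

  # fragment 250 bp, reads 101 bp: true overlap negative -> unmerged
  frag2 <- randomDNA(250)
  fwd2 <- ReadSet(DNAStringSet(c(p = substr(frag2, 1, 101))),
                  mate = "FORWARD")
  rev2 <- ReadSet(DNAStringSet(c(p = rcChr(substr(frag2, 150, 250)))),
                  mate = "REVERSE")
  mg2 <- mergePairs(fwd2, rev2, minOverlap = 10)
  expect_length(mg2$merged, 0L)
  expect_length(mg2$unmergedForward, 1L)

  # one mismatch in the overlap: the higher-quality base wins
  a <- "ACGTACGTACGTACG"
  b <- a
  substr(b, 8, 8) <- "G" # a has T at position 8
  qstr <- function(q, n) rawToChar(as.raw(rep(q + 33L, n)))
  fwd3 <- ReadSet(DNAStringSet(c(p = a)), qstr(40, nchar(a)),
                  mate = "FORWARD")
  rev3 <- ReadSet(DNAStringSet(c(p = rcChr(b))), qstr(10, nchar(b)),
                  mate = "REVERSE")
  mg3 <- mergePairs(fwd3, rev3, minOverlap = 5, maxMismatchFrac = 0.2)
  merged3 <- as.character(readSequences(mg3$merged))[[1]]
  expect_identical(substr(merged3, 8, 8), "T") # Q40 forward base won
})

test_that("independent consensus oracle agrees on disagreeing overlaps", {
  # re-implementation of the consensus rule: higher quality wins, ties take
  # the forward base; quality = max(2, |q1-q2|) at mismatches
  set.seed(11)
  for (rep in 1:5) {
    L <- 40
    fragA <- randomDNA(L)
    fragB <- fragA
    pos <- sample(10:30, 1)
    substr(fragB, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                       substr(fragA, pos, pos))[1]
    qf <- sample(5:40, L, replace = TRUE)
    qr <- sample(5:40, L, replace = TRUE)
    fwdRS <- ReadSet(DNAStringSet(c(p = fragA)),
                     rawToChar(as.raw(qf + 33L)), mate = "FORWARD")
    revRS <- ReadSet(DNAStringSet(c(p = rcChr(fragB))),
                     rawToChar(as.raw(base::rev(qr) + 33L)),
                     mate = "REVERSE")
    mg <- mergePairs(fwdRS, revRS, minOverlap = 10, maxMismatchFrac = 0.1)
    merged <- as.character(readSequences(mg$merged))[[1]]
    want <- if (qr[pos] > qf[pos]) substr(fragB, pos, pos)
            else substr(fragA, pos, pos)
    expect_identical(substr(merged, pos, pos), want)
    q <- as(readQualities(mg$merged), "IntegerList")[[1]]
    expect_equal(q[pos], max(2L, abs(qf[pos] - qr[pos])))
  }
})

test_that("prepareModes builds the three treatments with correct counts", {
  set.seed(3)
  frags <- vapply(1:10, function(i) randomDNA(60), character(1))
  ids <- sprintf("p%02d", 1:10)
  fwd <- ReadSet(DNAStringSet(setNames(substr(frags, 1, 40), ids)),
                 mate = "FORWARD")
  rev <- ReadSet(DNAStringSet(setNames(rcChr(substr(frags, 21, 60)), ids)),
                 mate = "REVERSE")
  modes <- prepareModes(fwd, rev, minOverlap = 10)
  expect_length(modes$merged, 10L)   # all mergeable
  expect_length(modes$paired, 20L)   # 10 pairs
  expect_length(modes$combined, 20L)
  expect_identical(readMode(modes$merged), "MERGED")
  expect_identical(readMode(modes$paired), "PAIRED")

  # an orphan pair member: dropped from PAIRED, kept in COMBINED
  orphan <- prepareModes(fwd, rev[1:9], minOverlap = 10)
  expect_length(orphan$paired, 18L)
  expect_length(orphan$combined, 19L)
  expect_true("p10/1" %in% readIds(orphan$combined))

  empty <- prepareModes(fwd[0], rev[0])
  expect_length(empty$merged, 0L)
  expect_length(empty$paired, 0L)
  expect_length(empty$combined, 0L)
})

test_that("merged-read lengths equal fragment lengths on clean libraries", {
  tl <- tinyLibrary(seed = 19, genomeLength = 5000, coverage = 8)
  prep <- preprocessReads(tl$lib$forward, tl$lib$reverse, tl$cfg@adapter)
  expect_identical(sort(width(readSequences(prep$merged))),
                   sort(width(tl$lib$fragments)))
  # and the sequences themselves are the fragments
  m <- prep$merged
  fr <- as.character(tl$lib$fragments)[match(readIds(m),
                                             names(tl$lib$fragments))]
  expect_identical(unname(as.character(readSequences(m))), unname(fr))
  # histograms agree
  h1 <- readLengthHistogram(m)
  h2 <- readLengthHistogram(tl$lib$fragments)
  expect_identical(h1, h2)
})
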