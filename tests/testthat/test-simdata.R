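test_that("genome simulation honours length, repeats and determinism", {
  cfg <- simConfig(genomeLength = 1000, targetCoverage = 0, seed = 3)
  g <- simulateGenome(cfg)
  expect_s4_class(g, "AnnotatedGenome")
  expect_equal(length(g), 1000L)
  expect_length(repeatRanges(g), 0L)

  cfg2 <- simConfig(genomeLength = 3000,
                    repeatSpecs = data.frame(unitLength = 100, copies = 2,
                                             divergence = 0),
                    seed = 3)
  g2 <- simulateGenome(cfg2)
  rr <- repeatRanges(g2)
  expect_length(rr, 2L)
  expect_true(all(width(rr) == 100L))
  copies <- as.character(Views(genomeSeq(g2), ranges(rr)))
  expect_identical(copies[1], copies[2]) # divergence 0 forces identity

  g2b <- simulateGenome(cfg2)
  expect_identical(as.character(genomeSeq(g2)),
                   as.character(genomeSeq(g2b)))

  # configuration in which the repeats cannot fit is rejected outright
  expect_error(simConfig(genomeLength = 250,
                         repeatSpecs = data.frame(unitLength = 100,
                                                  copies = 3,
                                                  divergence = 0),
                         seed = 1),
               "do not fit")
})

test_that("fragment lengths respect the configured model", {
  cfg <- simConfig(genomeLength = 30000, targetCoverage = 30,
                   fragmentMin = 44, fragmentMax = 172,
                   fragmentMean = 88, fragmentSd = 20, seed = 9)
  g <- simulateGenome(cfg)
  fr <- simulateFragments(g, cfg)
  w <- width(fr)
  expect_true(all(w >= 44 & w <= 172))
  expect_equal(length(fr),
               round(30 * 30000 / 88), tolerance = 0.1)
  # central-limit check against the configured mean
  se <- 20 / sqrt(length(fr))
  expect_lt(abs(mean(w) - 88), 3 * se + 0.2) # +0.2: clipping shifts slightly

  cfg0 <- simConfig(genomeLength = 5000, targetCoverage = 0, seed = 9)
  expect_length(simulateFragments(simulateGenome(cfg0), cfg0), 0L)

  bad <- simConfig(genomeLength = 5000, seed = 1)
  bad@fragmentMean <- 500
  expect_error(simulateFragments(g, bad), "fragmentMean")
})

test_that("fragments are exact genome substrings and same seed reproduces", {
  tl <- tinyLibrary(seed = 21, genomeLength = 4000, coverage = 5)
  gseq <- as.character(genomeSeq(tl$lib$genome))
  frs <- as.character(tl$lib$fragments)
  ori <- fragmentOrigin(tl$lib$fragments)
  for (i in seq_len(50)) {
    sub <- substr(gseq, ori$start[i] + 1L, ori$end[i])
    expected <- if (ori$strand[i] == "-") rcChr(sub) else sub
    expect_identical(frs[[i]], expected)
  }
  tl2 <- tinyLibrary(seed = 21, genomeLength = 4000, coverage = 5)
  expect_identical(as.character(tl2$lib$fragments), frs)
})

test_that("damage model follows rate * decay^offset and respects edge cases", {
  frag <- FragmentSet(DNAStringSet(c(f1 = "CCCCAGGT")), genome = "g",
                      start = 0L, end = 8L, strand = "+")

  cfg0 <- simConfig(damageRate5p = 0, seed = 1)
  expect_identical(as.character(applyDamage(frag, cfg0)), c(f1 = "CCCCAGGT"))

  cfg1 <- simConfig(damageRate5p = 1, damageDecay = 0, seed = 1)
  out <- as.character(applyDamage(frag, cfg1))[[1]]
  # exactly the position-0 C flips; the terminal G->A flips symmetrically at
  # the 3' terminus but this fragment ends in T, so offset 0 is untouched
  expect_identical(out, "TCCCAGGT")

  cfgU <- simConfig(damageRate5p = 0.3, seed = 4, udg = TRUE)
  expect_equal(cfgU@damageRate5p, 0)
})

test_that("paired-end sequencing implements adapter read-through", {
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
  cfg <- simConfig(readLength = 101, adapter = adapter, errorRate = 0,
                   damageRate5p = 0, seed = 2)
  frag60 <- paste(rep(c("A", "C", "G", "T", "G"), 12), collapse = "")
  fs <- FragmentSet(DNAStringSet(c(f = frag60)), genome = "g", start = 0L,
                    end = 60L, strand = "+")
  rd <- sequencePairedEnd(fs, cfg)
  fwd <- as.character(readSequences(rd$forward))[[1]]
  rev <- as.character(readSequences(rd$reverse))[[1]]
  expect_equal(nchar(fwd), 101L)
  expect_identical(substr(fwd, 1, 60), frag60)
  expect_identical(substr(fwd, 61, 93), adapter)
  expect_identical(substr(fwd, 94, 101), "AAAAAAAA") # Q2 'A' padding
  expect_identical(substr(rev, 1, 60), rcChr(frag60))
  expect_identical(substr(rev, 61, 93), adapter)
  # padding quality is Q2
  q <- as(readQualities(rd$forward), "IntegerList")[[1]]
  expect_true(all(q[94:101] == 2L))
  expect_true(all(q[1:93] == 37L))

  frag150 <- randomDNA(150)
  fs2 <- FragmentSet(DNAStringSet(c(f = frag150)), genome = "g", start = 0L,
                     end = 150L, strand = "+")
  rd2 <- sequencePairedEnd(fs2, cfg)
  fwd2 <- as.character(readSequences(rd2$forward))[[1]]
  rev2 <- as.character(readSequences(rd2$reverse))[[1]]
  expect_identical(fwd2, substr(frag150, 1, 101))  # exact prefix, no noise
  expect_identical(rcChr(rev2), substr(frag150, 50, 150))
  # forward and reverse overlap by 101 + 101 - 150 = 52 bases
  expect_identical(substr(fwd2, 99, 101), substr(rcChr(rev2), 50, 52))
})

test_that("full simulation is a pure function of the seed (FASTQ bytes)", {
  d1 <- tempfile(); d2 <- tempfile()
  tl <- tinyLibrary(seed = 77, genomeLength = 2000, coverage = 3)
  writeSimulatedLibrary(tl$lib, d1)
  writeSimulatedLibrary(simulateLibrary(tl$cfg), d2)
  for (f in c("sim_R1.fastq", "sim_R2.fastq", "sim_genome.fasta")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero-noise reads are substrings of fragment+adapter construction", {
  tl <- tinyLibrary(seed = 13, genomeLength = 2000, coverage = 4)
  lib <- tl$lib
  adapter <- tl$cfg@adapter
  frs <- as.character(lib$fragments)
  fwd <- as.character(readSequences(lib$forward))
  for (i in seq_len(min(100, length(fwd)))) {
    tpl <- paste0(frs[i], adapter, strrep("A", 101))
    expect_identical(fwd[[i]], substr(tpl, 1, 101))
  }
})
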