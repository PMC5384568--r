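# independent brute-force oracles and small fixture builders used across the
# suite; everything here is deliberately naive

suppressPackageStartupMessages({
  library(Biostrings)
  library(IRanges)
  library(GenomicRanges)
})

rcChr <- function(s) {
  as.character(reverseComplement(DNAStringSet(s)))
}

canonChr <- function(s) {
  r <- rcChr(s)
  ifelse(s <= r, s, r)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# hand enumeration of canonical k-mer multiplicities
oracleKmers <- function(reads, k) {
  out <- unlist(lapply(reads, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    km <- substring(s, 1:(n - k + 1L), k:n)
    km[!grepl("[^ACGT]", km)]
  }))
  if (!length(out)) return(integer())
  out <- canonChr(out)
  tab <- table(out)
  setNames(as.integer(tab), names(tab))
}

# direct evaluation of the N50 definition: largest L such that contigs of
# length >= L sum to at least half the total
oracleN50 <- function(w) {
  if (!length(w)) return(0)
  tot <- sum(w)
  cand <- sort(unique(w), decreasing = TRUE)
  for (L in cand) if (sum(w[w >= L]) >= tot / 2) return(L)
  min(w)
}

# maximal exact suffix-prefix overlap by direct substring comparison,
# capped below containment
oracleOverlap <- function(a, b, minOverlap) {
  hi <- min(nchar(a), nchar(b)) - 1L
  if (hi < minOverlap) return(0L)
  for (L in hi:minOverlap) {
    if (substr(a, nchar(a) - L + 1L, nchar(a)) == substr(b, 1L, L))
      return(L)
  }
  0L
}

# all-pairs oriented overlap scan in the same format as the fast index
oracleAllOverlaps <- function(seqs, minOverlap) {
  n <- length(seqs)
  rows <- list()
  for (q in seq_len(n)) for (t in seq_len(n)) {
    if (q == t) next
    for (qo in 0:1) for (to in 0:1) {
      a <- if (qo == 0) seqs[q] else rcChr(seqs[q])
      b <- if (to == 0) seqs[t] else rcChr(seqs[t])
      if (min(nchar(a), nchar(b)) - 1L < minOverlap) next
      L <- oracleOverlap(a, b, minOverlap)
      if (L >= minOverlap)
        rows[[length(rows) + 1L]] <-
          data.frame(from = q, fromOrient = qo, to = t, toOrient = to,
                     length = L)
    }
  }
  if (!length(rows))
    return(data.frame(from = integer(), fromOrient = integer(),
                      to = integer(), toOrient = integer(),
                      length = integer()))
  do.call(rbind, rows)
}

# per-base boolean coverage oracle over 1-based closed intervals
oracleCoverageMask <- function(starts, ends, G) {
  mask <- rep(FALSE, G)
  for (i in seq_along(starts)) {
    if (ends[i] >= starts[i]) mask[starts[i]:ends[i]] <- TRUE
  }
  mask
}

oracleGapCount <- function(mask) {
  r <- rle(mask)
  sum(!r$values)
}

isSubstringEitherStrand <- function(x, genome) {
  grepl(x, genome, fixed = TRUE) || grepl(x, rcChr(genome), fixed = TRUE)
}

# small error-free library used by several files
tinyLibrary <- function(seed = 5L, genomeLength = 6000L, coverage = 25L,
                        repeats = NULL) {
  if (is.null(repeats))
    repeats <- data.frame(unitLength = integer(), copies = integer(),
                          divergence = numeric())
  cfg <- simConfig(genomeLength = genomeLength, repeatSpecs = repeats,
                   targetCoverage = coverage, errorRate = 0,
                   damageRate5p = 0, seed = seed)
  list(cfg = cfg, lib = simulateLibrary(cfg))
}
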