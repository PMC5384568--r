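#' @include AllClasses.R
NULL

#' Clip adapter read-through from the 3' end of reads
#'
#' Finds, for each read, the leftmost position at which the remainder of the
#' read matches a prefix of the adapter (semi-global suffix-prefix
#' alignment, match length at least \code{minOverlap}, mismatch fraction at
#' most \code{maxMismatchFrac}; internal full adapter occurrences are
#' covered by the same scan) and removes that suffix together with its
#' qualities; the scan is repeated to a fixpoint, so the operation is
#' idempotent. Reads without an admissible match are returned unchanged.
#' The default minimum match length of 1 clips even single-base adapter
#' remnants: fragments one or two bases shorter than the read length
#' otherwise retain adapter bases that prevent their pair from merging.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param adapter adapter sequence.
#' @param minOverlap minimum read/adapter match length (default 1).
#' @param maxMismatchFrac tolerated mismatch fraction in the match
#'   (default 0.1).
#' @return The clipped \linkS4class{ReadSet} (same reads, possibly shorter).
#' @export
clipAdapter <- function(reads, adapter, minOverlap = 1L,
                        maxMismatchFrac = 0.1) {
  stopifnot(is(reads, "ReadSet"), minOverlap >= 1L)
  if (!length(reads)) return(reads)
  keep <- cpp_clip_positions(as.character(readSequences(reads)),
                             adapter, as.integer(minOverlap),
                             maxMismatchFrac)
  initialize(reads,
             sequences = Biostrings::subseq(readSequences(reads), 1L,
                                            keep),
             qualities = Biostrings::subseq(readQualities(reads), 1L, keep))
}

#' Trim low-quality 3' ends and discard too-short reads
#'
#' Removes 3'-terminal bases whose quality is below \code{qThreshold};
#' reads falling below \code{minLength} afterwards are discarded.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param qThreshold Phred threshold (default 20).
#' @param minLength minimum surviving read length (default 25).
#' @return The trimmed \linkS4class{ReadSet}; discarded reads are dropped.
#' @export
qualityTrim <- function(reads, qThreshold = 20L, minLength = 25L) {
  stopifnot(is(reads, "ReadSet"), qThreshold >= 0L)
  if (!length(reads)) return(reads)
  keep <- cpp_qtrim_lengths(as.character(readQualities(reads)),
                            as.integer(qThreshold))
  out <- initialize(reads,
                    sequences = Biostrings::subseq(readSequences(reads), 1L,
                                                   keep),
                    qualities = Biostrings::subseq(readQualities(reads), 1L,
                                                   keep))
  out[BiocGenerics::width(readSequences(out)) >= minLength]
}

#' Merge overlapping forward/reverse read pairs
#'
#' The reverse read is reverse-complemented and the best suffix(forward) /
#' prefix(reverse-complement) overlap with length at least \code{minOverlap}
#' and mismatch fraction at most \code{maxMismatchFrac} is selected (score =
#' matches - mismatches, ties broken towards the longest overlap). At
#' disagreeing overlap positions the higher-quality base wins (quality
#' max(2, |q1-q2|)); agreements take the maximum quality. Pairs without an
#' admissible overlap are returned unmerged.
#'
#' @param fwd,rev \linkS4class{ReadSet}s with matching ids (pairs are
#'   matched by read id).
#' @param minOverlap minimum overlap length (default 10).
#' @param maxMismatchFrac tolerated overlap mismatch fraction (default
#'   0.05).
#' @return list(merged = ReadSet of MERGED reads, unmergedForward,
#'   unmergedReverse = the reads of pairs that could not be merged).
#' @export
mergePairs <- function(fwd, rev, minOverlap = 10L, maxMismatchFrac = 0.05) {
  stopifnot(is(fwd, "ReadSet"), is(rev, "ReadSet"))
  ids <- intersect(readIds(fwd), readIds(rev))
  fwd <- fwd[match(ids, readIds(fwd))]
  rev <- rev[match(ids, readIds(rev))]
  if (!length(ids)) {
    return(list(merged = ReadSet(DNAStringSet(), mate = "MERGED",
                                 mode = "MERGED"),
                unmergedForward = fwd, unmergedReverse = rev))
  }
  res <- cpp_merge_pairs(as.character(readSequences(fwd)),
                         as.character(readQualities(fwd)),
                         as.character(readSequences(rev)),
                         as.character(readQualities(rev)),
                         as.integer(minOverlap), maxMismatchFrac)
  ok <- res$merged
  merged <- ReadSet(DNAStringSet(setNames(res$seq[ok], ids[ok])),
                    res$qual[ok], mate = "MERGED", mode = "MERGED")
  list(merged = merged,
       unmergedForward = fwd[!ok],
       unmergedReverse = rev[!ok])
}

#' Build the three preprocessing modes from clipped and trimmed reads
#'
#' Given complete pairs (matched by id across \code{fwd}/\code{rev}) and any
#' orphan singletons, constructs the three read treatments used downstream:
#' \itemize{
#'   \item MERGED: merged pairs, plus both reads of unmergeable pairs as
#'     singles, plus the singletons;
#'   \item PAIRED: complete pairs only, unmerged; orphans dropped;
#'   \item COMBINED: every surviving read (orphans kept), re-identified with
#'     globally unique ids (\code{/1}, \code{/2} suffixes).
#' }
#'
#' @param fwd,rev \linkS4class{ReadSet}s of already clipped/trimmed reads;
#'   ids present in both form the complete pairs, the rest are orphans.
#' @param singletons optional \linkS4class{ReadSet} of additional single
#'   reads.
#' @param minOverlap,maxMismatchFrac merging parameters, see
#'   \code{\link{mergePairs}}.
#' @return list(merged, paired, combined) of \linkS4class{ReadSet}s plus a
#'   \code{log} data.frame of per-mode read counts.
#' @export
prepareModes <- function(fwd, rev, singletons = NULL, minOverlap = 10L,
                         maxMismatchFrac = 0.05) {
  stopifnot(is(fwd, "ReadSet"), is(rev, "ReadSet"))
  ids <- intersect(readIds(fwd), readIds(rev))
  orphanF <- fwd[!(readIds(fwd) %in% ids)]
  orphanR <- rev[!(readIds(rev) %in% ids)]
  pairF <- fwd[match(ids, readIds(fwd))]
  pairR <- rev[match(ids, readIds(rev))]

  mg <- mergePairs(pairF, pairR, minOverlap, maxMismatchFrac)

  asSingle <- function(x, suffix) {
    s <- readSequences(x)
    if (length(s)) names(s) <- paste0(names(s), suffix)
    ReadSet(s, as.character(readQualities(x)), mate = "SINGLE",
            mode = "RAW")
  }
  singles <- list(asSingle(mg$unmergedForward, "/1"),
                  asSingle(mg$unmergedReverse, "/2"),
                  asSingle(orphanF, "/1"), asSingle(orphanR, "/2"))
  if (!is.null(singletons)) singles <- c(singles, list(singletons))

  mergedSet <- .bindReadSets(c(list(mg$merged), singles), mode = "MERGED",
                             mate = NULL)

  pairedSet <- .bindReadSets(list(pairF, pairR), mode = "PAIRED",
                             mate = NULL)

  combined <- .bindReadSets(c(list(asSingle(pairF, "/1"),
                                   asSingle(pairR, "/2"),
                                   asSingle(orphanF, "/1"),
                                   asSingle(orphanR, "/2")),
                              if (is.null(singletons)) NULL
                              else list(singletons)),
                            mode = "COMBINED", mate = "SINGLE")
  if (anyDuplicated(readIds(combined)))
    stop("duplicate read ids in COMBINED mode")

  log <- data.frame(
    mode = c("MERGED", "PAIRED", "COMBINED"),
    pairsIn = length(ids),
    merged = length(mg$merged),
    orphans = length(orphanF) + length(orphanR),
    reads = c(length(mergedSet), length(pairedSet), length(combined)))
  list(merged = mergedSet, paired = pairedSet, combined = combined,
       log = log)
}

.bindReadSets <- function(sets, mode, mate = NULL) {
  sets <- Filter(function(x) length(x) > 0L, sets)
  if (!length(sets)) {
    return(ReadSet(DNAStringSet(),
                   mate = if (is.null(mate)) "SINGLE" else mate,
                   mode = mode))
  }
  seqs <- do.call(c, lapply(sets, readSequences))
  quals <- unlist(lapply(sets, function(x)
    as.character(readQualities(x))))
  mates <- if (is.null(mate)) unlist(lapply(sets, mateRoles)) else mate
  ReadSet(seqs, quals, mate = mates, mode = mode)
}

#' Full preprocessing: clip, trim, and build the three modes
#'
#' @param fwd,rev raw \linkS4class{ReadSet}s (paired by id).
#' @param adapter adapter sequence.
#' @param clipMinOverlap,clipMaxMismatch adapter clipping parameters.
#' @param qThreshold,minLength quality trimming parameters.
#' @param mergeMinOverlap,mergeMaxMismatch pair merging parameters.
#' @return As \code{\link{prepareModes}}.
#' @export
preprocessReads <- function(fwd, rev, adapter,
                            clipMinOverlap = 1L, clipMaxMismatch = 0.1,
                            qThreshold = 20L, minLength = 25L,
                            mergeMinOverlap = 10L, mergeMaxMismatch = 0.05) {
  fwd <- qualityTrim(clipAdapter(fwd, adapter, clipMinOverlap,
                                 clipMaxMismatch),
                     qThreshold, minLength)
  rev <- qualityTrim(clipAdapter(rev, adapter, clipMinOverlap,
                                 clipMaxMismatch),
                     qThreshold, minLength)
  prepareModes(fwd, rev, minOverlap = mergeMinOverlap,
               maxMismatchFrac = mergeMaxMismatch)
}
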