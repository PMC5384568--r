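#' @include AllClasses.R
NULL

#' Map contigs to a reference genome
#'
#' Seed-chain-extend local alignment of each contig (both strands) against
#' the reference: exact seeds grouped by diagonal, ungapped X-drop
#' extension, split alignments permitted; accepted alignments are
#' non-overlapping on the contig and have identity at least
#' \code{minIdentity}.
#'
#' @param contigs a \linkS4class{ContigSet}.
#' @param reference an \linkS4class{AnnotatedGenome}.
#' @param minIdentity minimum alignment identity (default 0.9).
#' @param seedLength exact seed length (default 31).
#' @return A \link[GenomicRanges]{GRanges} on the reference (1-based) with
#'   metadata columns \code{contig}, \code{identity}, \code{qstart},
#'   \code{qend} (0-based half-open on the contig).
#' @export
mapContigsToReference <- function(contigs, reference, minIdentity = 0.9,
                                  seedLength = 31L) {
  stopifnot(is(contigs, "ContigSet"), is(reference, "AnnotatedGenome"))
  if (!length(reference@sequence)) stop("reference must be non-empty")
  sl <- setNames(length(reference@sequence), reference@id)
  if (!length(contigs))
    return(GenomicRanges::GRanges(seqlengths = sl))
  hits <- cpp_map_contigs(as.character(contigs),
                          as.character(reference@sequence),
                          as.integer(seedLength), minIdentity)
  GenomicRanges::GRanges(
    seqnames = rep(reference@id, nrow(hits)),
    ranges = IRanges::IRanges(start = hits$rstart + 1L, end = hits$rend),
    strand = hits$strand,
    contig = names(contigs)[hits$contig],
    identity = hits$identity,
    qstart = hits$qstart, qend = hits$qend,
    seqlengths = sl)
}

#' Contig length statistics
#'
#' Statistics over contigs of length at least \code{minLength}. N50 is the
#' largest L such that contigs of length >= L sum to at least half the
#' total assembly length (computed over the filtered set).
#'
#' @param contigs a \linkS4class{ContigSet} (or numeric vector of lengths).
#' @param minLength length cutoff in bp (default 0).
#' @return list(count, n50, mean, longest, empty).
#' @export
contigStats <- function(contigs, minLength = 0L) {
  w <- if (is.numeric(contigs)) contigs else BiocGenerics::width(contigs)
  w <- w[w >= minLength]
  if (!length(w))
    return(list(count = 0L, n50 = 0, mean = 0, longest = 0, empty = TRUE))
  list(count = length(w), n50 = .n50(w), mean = mean(w), longest = max(w),
       empty = FALSE)
}

#' Reference gap analysis
#'
#' The union of aligned reference intervals is computed; gaps are the
#' maximal uncovered intervals (any length >= 1 bp counts as one gap) and
#' the covered fraction is union length / reference length.
#'
#' @param alignments GRanges from \code{\link{mapContigsToReference}}.
#' @param reference an \linkS4class{AnnotatedGenome}.
#' @return list(nGaps, gaps = GRanges, coveredFraction).
#' @export
gapAnalysis <- function(alignments, reference) {
  stopifnot(is(reference, "AnnotatedGenome"))
  G <- length(reference@sequence)
  covered <- IRanges::reduce(IRanges::ranges(alignments))
  gapR <- IRanges::gaps(covered, start = 1L, end = G)
  gaps <- GenomicRanges::GRanges(seqnames = rep(reference@id, length(gapR)),
                                 ranges = gapR,
                                 seqlengths = setNames(G, reference@id))
  list(nGaps = length(gapR), gaps = gaps,
       coveredFraction = sum(BiocGenerics::width(covered)) / G)
}

#' Genome coverage as a function of the minimum contig length
#'
#' For each threshold t, the covered reference fraction is recomputed using
#' only alignments of contigs of length at least t. The curve is
#' non-increasing in t.
#'
#' @param alignments GRanges from \code{\link{mapContigsToReference}}.
#' @param contigs the \linkS4class{ContigSet} that was mapped.
#' @param reference an \linkS4class{AnnotatedGenome}.
#' @param thresholds ascending length thresholds in bp; default 1000 to
#'   10000 in steps of 500.
#' @return data.frame(threshold, fraction).
#' @export
coverageByMinLength <- function(alignments, contigs, reference,
                                thresholds = seq(1000L, 10000L, by = 500L)) {
  stopifnot(!is.unsorted(thresholds))
  G <- length(reference@sequence)
  w <- setNames(BiocGenerics::width(contigs), names(contigs))
  clen <- w[alignments$contig]
  frac <- vapply(thresholds, function(t) {
    keep <- clen >= t
    sum(BiocGenerics::width(IRanges::reduce(
      IRanges::ranges(alignments[keep])))) / G
  }, numeric(1))
  data.frame(threshold = as.integer(thresholds), fraction = frac)
}

#' Unresolved-repeat fraction
#'
#' The fraction of annotated repeat bases that fall into assembly gaps:
#' bases in the intersection of the gap intervals with the repeat intervals,
#' divided by the total annotated repeat bases.
#'
#' @param gaps GRanges of gaps (from \code{\link{gapAnalysis}}).
#' @param repeats GRanges of annotated repeats on the same reference.
#' @return The unresolved fraction, or NA when no repeat bases are
#'   annotated.
#' @export
repeatResolution <- function(gaps, repeats) {
  repR <- IRanges::reduce(IRanges::ranges(repeats))
  tot <- sum(BiocGenerics::width(repR))
  if (tot == 0L) return(NA_real_)
  inter <- IRanges::intersect(IRanges::reduce(IRanges::ranges(gaps)), repR)
  sum(BiocGenerics::width(inter)) / tot
}

#' Read length histogram
#'
#' @param reads a \linkS4class{ReadSet} (or DNAStringSet).
#' @return data.frame(length, count), sorted by length; total count equals
#'   the number of reads.
#' @export
readLengthHistogram <- function(reads) {
  w <- if (is(reads, "ReadSet")) BiocGenerics::width(readSequences(reads))
       else BiocGenerics::width(reads)
  if (!length(w))
    return(data.frame(length = integer(), count = integer()))
  tab <- table(w)
  data.frame(length = as.integer(names(tab)), count = as.integer(tab))
}

#' Full reference-based evaluation of one assembly
#'
#' Maps the contigs, computes Table-style statistics over mapped contigs of
#' at least \code{minLength}, the gap analysis restricted to those contigs,
#' the coverage-by-minimum-length curve and the unresolved-repeat fraction.
#'
#' @param contigs a \linkS4class{ContigSet}.
#' @param reference an \linkS4class{AnnotatedGenome}.
#' @param label assembly name recorded in the report.
#' @param minLength evaluation length cutoff in bp (default 1000).
#' @param thresholds thresholds for the coverage curve.
#' @param minIdentity mapping identity cutoff (default 0.9).
#' @return An \linkS4class{AssemblyReport}.
#' @export
assemblyReport <- function(contigs, reference, label = "assembly",
                           minLength = 1000L,
                           thresholds = seq(1000L, 10000L, by = 500L),
                           minIdentity = 0.9) {
  aln <- mapContigsToReference(contigs, reference, minIdentity)
  mapped <- unique(aln$contig)
  w <- setNames(BiocGenerics::width(contigs), names(contigs))
  eligible <- mapped[w[mapped] >= minLength]
  st <- contigStats(unname(w[eligible]), minLength = 0L)
  alnUse <- aln[aln$contig %in% eligible]
  ga <- gapAnalysis(alnUse, reference)
  curve <- coverageByMinLength(aln, contigs, reference, thresholds)
  rr <- repeatResolution(ga$gaps, reference@repeats)
  new("AssemblyReport", label = label,
      nContigs = as.integer(st$count), n50 = as.numeric(st$n50),
      meanLength = as.numeric(st$mean), longest = as.numeric(st$longest),
      nGaps = as.integer(ga$nGaps),
      coveredFraction = ga$coveredFraction,
      coverageCurve = curve, repeatUnresolved = rr, gaps = ga$gaps)
}
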