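#' @include AllClasses.R
NULL

.asSeqChar <- function(reads) {
  if (is(reads, "ReadSet")) as.character(readSequences(reads))
  else if (is(reads, "XStringSet")) as.character(reads)
  else as.character(reads)
}

#' Build a de Bruijn graph from reads
#'
#' Every length-k substring of every read contributes one multiplicity count
#' to its canonical k-mer (both strands are represented through
#' canonicalization). Reads shorter than k contribute nothing; k-mers
#' containing non-ACGT characters are skipped. k must be odd so no k-mer is
#' its own reverse complement.
#'
#' @param reads a \linkS4class{ReadSet}, DNAStringSet or character vector.
#' @param k odd k-mer size, \code{3 <= k}.
#' @return A \linkS4class{KmerGraph}.
#' @export
buildGraph <- function(reads, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L)
    stop("k must be odd (even k allows palindromic k-mers)")
  if (k < 3L) stop("k must be >= 3")
  res <- cpp_count_kmers(.asSeqChar(reads), k)
  new("KmerGraph", k = k, kmers = as.character(res$kmers),
      counts = as.integer(res$counts))
}

#' Clean a de Bruijn graph
#'
#' Removes edges with multiplicity below \code{minCoverage}, iteratively
#' clips dead-end paths (tips) spelling fewer than \code{maxTipLength} bp,
#' and collapses simple two-path bubbles with identical flanking k-mers onto
#' the higher-coverage path.
#'
#' @param graph a \linkS4class{KmerGraph}.
#' @param minCoverage minimum edge multiplicity (default 2).
#' @param maxTipLength maximum spelled length of a clipped tip in bp
#'   (default 2k).
#' @return The cleaned \linkS4class{KmerGraph}.
#' @export
cleanGraph <- function(graph, minCoverage = 2L, maxTipLength = NULL) {
  stopifnot(is(graph, "KmerGraph"), minCoverage >= 0L)
  if (is.null(maxTipLength)) maxTipLength <- 2L * graph@k
  stopifnot(maxTipLength >= 0L)
  res <- cpp_clean_graph(graph@kmers, graph@counts, graph@k,
                         as.integer(minCoverage),
                         as.integer(maxTipLength))
  new("KmerGraph", k = graph@k, kmers = as.character(res$kmers),
      counts = as.integer(res$counts))
}

#' Extract unitig contigs from a de Bruijn graph
#'
#' Contigs are the spellings of maximal unbranched paths of the bidirected
#' graph; every k-mer is spelled exactly once. Output is deterministic:
#' contigs are emitted in the lexicographically smaller of the two
#' orientations and sorted.
#'
#' @param graph a (cleaned) \linkS4class{KmerGraph}.
#' @param k label recorded in the contig provenance; defaults to the
#'   graph's k.
#' @return A layer-1 \linkS4class{ContigSet}.
#' @export
extractContigs <- function(graph, k = kmerSize(graph)) {
  stopifnot(is(graph, "KmerGraph"))
  seqs <- cpp_extract_contigs(graph@kmers, graph@counts, graph@k)
  if (length(seqs))
    names(seqs) <- sprintf("L1|k%d|%04d", k, seq_along(seqs))
  ContigSet(DNAStringSet(seqs), layer = 1L, k = k)
}

#' Multi-k first-layer assembly
#'
#' Runs one independent de Bruijn assembly (build, clean, extract) per k-mer
#' size. A k larger than every read yields an empty assembly with a warning.
#' Paired-end information is not used: reads are assembled as singles
#' regardless of mode.
#'
#' @param reads a \linkS4class{ReadSet} (or DNAStringSet).
#' @param kList odd k-mer sizes; default 37, 47, ..., 127.
#' @param minCoverage,maxTipLength cleaning parameters (maxTipLength
#'   defaults to 2k per assembly).
#' @param clean set FALSE to skip graph cleaning.
#' @return Named list (\code{k37}, \code{k47}, ...) of layer-1
#'   \linkS4class{ContigSet}s.
#' @export
multiKAssemble <- function(reads, kList = seq(37L, 127L, by = 10L),
                           minCoverage = 2L, maxTipLength = NULL,
                           clean = TRUE) {
  kList <- as.integer(kList)
  if (!length(kList)) stop("kList must be non-empty")
  if (any(kList %% 2L == 0L)) stop("all k in kList must be odd")
  out <- lapply(kList, function(k) {
    g <- buildGraph(reads, k)
    if (clean) g <- cleanGraph(g, minCoverage, maxTipLength)
    contigs <- extractContigs(g, k = k)
    if (!length(contigs))
      warning("assembly with k = ", k, " produced no contigs",
              call. = FALSE)
    contigs
  })
  names(out) <- paste0("k", kList)
  out
}

#' Summarise a list of layer-1 assemblies
#'
#' @param assemblies result of \code{\link{multiKAssemble}}.
#' @return data.frame(k, nContigs, totalBp, n50).
#' @export
assemblySummary <- function(assemblies) {
  do.call(rbind, lapply(names(assemblies), function(nm) {
    w <- BiocGenerics::width(assemblies[[nm]])
    data.frame(k = as.integer(sub("^k", "", nm)), nContigs = length(w),
               totalBp = sum(w), n50 = .n50(w))
  }))
}

# N50: largest L such that contigs of length >= L sum to >= half the total
.n50 <- function(w) {
  if (!length(w)) return(0)
  w <- sort(w, decreasing = TRUE)
  w[which(cumsum(w) >= sum(w) / 2)[1L]]
}
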