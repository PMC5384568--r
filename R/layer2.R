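#' @include AllClasses.R
NULL

#' Pool contigs from several first-layer assemblies
#'
#' Concatenates the assemblies into one contig set; ids (already unique per
#' assembly through the \code{L1|k<K>|<serial>} scheme) must be globally
#' unique and provenance is preserved.
#'
#' @param assemblies list of \linkS4class{ContigSet}s (e.g. from
#'   \code{\link{multiKAssemble}}), empty ones allowed.
#' @return A pooled \linkS4class{ContigSet}.
#' @export
poolContigs <- function(assemblies) {
  assemblies <- Filter(function(x) length(x) > 0L, assemblies)
  if (!length(assemblies))
    return(ContigSet(DNAStringSet(), layer = 1L))
  seqs <- do.call(c, unname(lapply(assemblies, function(x)
    DNAStringSet(setNames(as.character(x), names(x))))))
  mc <- do.call(rbind, lapply(assemblies, S4Vectors::mcols))
  if (anyDuplicated(names(seqs)))
    stop("contig id collision while pooling assemblies")
  S4Vectors::mcols(seqs) <- mc
  new("ContigSet", seqs)
}

#' Remove duplicate and contained contigs
#'
#' A contig whose sequence occurs as a substring of another pooled contig,
#' in either orientation, is removed (this covers exact duplicates and
#' reverse-complement duplicates). Among equal-length duplicates the contig
#' with the lexicographically smallest id survives.
#'
#' @param contigs a \linkS4class{ContigSet}.
#' @return The deduplicated \linkS4class{ContigSet}.
#' @export
removeDuplicates <- function(contigs) {
  stopifnot(is(contigs, "ContigSet"))
  if (length(contigs) < 2L) return(contigs)
  cont <- cpp_containments(as.character(contigs))
  if (!nrow(cont)) return(contigs)
  ids <- names(contigs)
  w <- BiocGenerics::width(contigs)
  drop <- (w[cont$contained] < w[cont$container]) |
    (cont$equal & ids[cont$contained] > ids[cont$container])
  contigs[!(seq_along(contigs) %in% cont$contained[drop])]
}

## physical-end bookkeeping for the bidirected overlap structure: the 3' end
## of the forward orientation is end "R", of the reverse orientation end "L".
.dedupEdges <- function(ov) {
  if (!nrow(ov)) return(ov)
  endF <- ifelse(ov$fromOrient == 0L, "R", "L")
  endT <- ifelse(ov$toOrient == 0L, "L", "R")
  k1 <- paste(ov$from, endF, ov$to, endT, ov$length)
  k2 <- paste(ov$to, endT, ov$from, endF, ov$length)
  ov[!duplicated(pmin(k1, k2)), , drop = FALSE]
}

#' Merge unambiguously overlapping contigs (FM-merge)
#'
#' Iteratively merges contig pairs joined by a maximal exact suffix-prefix
#' overlap of at least \code{minOverlap} bp when the overlap is unambiguous:
#' the involved end of each contig has no other overlap partner. Repeats to
#' fixpoint; the result is independent of the input order.
#'
#' @param contigs a deduplicated \linkS4class{ContigSet}.
#' @param minOverlap minimum exact overlap length in bp (default 45).
#' @return A \linkS4class{ContigSet} with unambiguous chains collapsed;
#'   merged contigs take the lexicographically smaller constituent id.
#' @export
fmMerge <- function(contigs, minOverlap = 45L) {
  stopifnot(is(contigs, "ContigSet"))
  seqs <- as.character(contigs)
  ids <- names(contigs)
  mc <- S4Vectors::mcols(contigs)
  layer <- mc$layer; kk <- mc$k; supp <- mc$support

  repeat {
    n <- length(seqs)
    if (n < 2L) break
    ov <- .dedupEdges(cpp_all_overlaps(seqs, as.integer(minOverlap)))
    if (!nrow(ov)) break
    endF <- ifelse(ov$fromOrient == 0L, "R", "L")
    endT <- ifelse(ov$toOrient == 0L, "L", "R")
    keyF <- paste(ov$from, endF)
    keyT <- paste(ov$to, endT)
    endUse <- table(c(keyF, keyT))
    mutual <- endUse[keyF] == 1L & endUse[keyT] == 1L
    cand <- which(mutual)
    if (!length(cand)) break
    ord <- cand[order(pmin(ids[ov$from[cand]], ids[ov$to[cand]]),
                      pmax(ids[ov$from[cand]], ids[ov$to[cand]]))]
    used <- logical(n)
    newSeq <- character(); newId <- character()
    consumed <- integer()
    for (i in ord) {
      a <- ov$from[i]; b <- ov$to[i]
      if (used[a] || used[b]) next
      used[a] <- used[b] <- TRUE
      aSeq <- if (ov$fromOrient[i] == 0L) seqs[a] else .revcompChr(seqs[a])
      bSeq <- if (ov$toOrient[i] == 0L) seqs[b] else .revcompChr(seqs[b])
      mSeq <- paste0(aSeq, substring(bSeq, ov$length[i] + 1L))
      mRc <- .revcompChr(mSeq)
      if (mRc < mSeq) mSeq <- mRc # canonical orientation for determinism
      newSeq <- c(newSeq, mSeq)
      newId <- c(newId, min(ids[a], ids[b]))
      consumed <- c(consumed, a, b)
    }
    if (!length(consumed)) break
    keep <- setdiff(seq_len(n), consumed)
    seqs <- c(seqs[keep], newSeq)
    ids <- c(ids[keep], newId)
    layer <- c(layer[keep], rep(1L, length(newId)))
    kk <- c(kk[keep], rep(NA_integer_, length(newId)))
    supp <- c(supp[keep], rep(NA_integer_, length(newId)))
    o <- order(ids)
    seqs <- seqs[o]; ids <- ids[o]
    layer <- layer[o]; kk <- kk[o]; supp <- supp[o]
  }
  ContigSet(DNAStringSet(setNames(seqs, ids)), layer = layer, k = kk,
            support = supp)
}

.revcompChr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Build the exact suffix-prefix overlap graph
#'
#' All maximal exact suffix-prefix overlaps of length at least
#' \code{minOverlap} between oriented contigs are detected (rolling-hash
#' scan whose output equals the all-pairs quadratic comparison); edges
#' implied by two consecutive shorter overlaps with consistent lengths are
#' marked reducible (transitive reduction).
#'
#' @param contigs a deduplicated, FM-merged \linkS4class{ContigSet}.
#' @param minOverlap minimum exact overlap length in bp (default 45).
#' @return An \linkS4class{OverlapGraph}.
#' @export
buildOverlapGraph <- function(contigs, minOverlap = 45L) {
  stopifnot(is(contigs, "ContigSet"))
  ov <- cpp_all_overlaps(as.character(contigs), as.integer(minOverlap))
  ov$reducible <- rep(FALSE, nrow(ov))
  if (nrow(ov) > 1L) {
    w <- BiocGenerics::width(contigs)
    ekey <- paste(ov$from, ov$fromOrient, ov$to, ov$toOrient)
    eidx <- setNames(seq_len(nrow(ov)), ekey)
    byFrom <- split(seq_len(nrow(ov)), paste(ov$from, ov$fromOrient))
    for (i in seq_len(nrow(ov))) {
      js <- byFrom[[paste(ov$to[i], ov$toOrient[i])]]
      if (is.null(js)) next
      for (j in js) {
        if (ov$to[j] == ov$from[i]) next
        implied <- ov$length[i] + ov$length[j] - w[ov$to[i]]
        if (implied < 1L) next
        k <- eidx[paste(ov$from[i], ov$fromOrient[i], ov$to[j],
                        ov$toOrient[j])]
        if (!is.na(k) && ov$length[k] == implied) ov$reducible[k] <- TRUE
      }
    }
    # keep complement edges consistent
    comp <- eidx[paste(ov$to, 1L - ov$toOrient, ov$from,
                       1L - ov$fromOrient)]
    red <- ov$reducible | (!is.na(comp) & ov$reducible[comp])
    ov$reducible <- red
  }
  new("OverlapGraph", contigs = contigs, edges = ov,
      minOverlap = as.integer(minOverlap))
}

#' Spell final contigs from the overlap graph
#'
#' Maximal unbranched paths over the irreducible edges are spelled into
#' layer-2 contigs (overlapping parts written once); paths terminate at
#' branch nodes, every contig appears in exactly one path, and contigs
#' shorter than \code{minFinalLength} are dropped. Output orientation and
#' order are deterministic.
#'
#' @param graph an \linkS4class{OverlapGraph}.
#' @param minFinalLength minimum final contig length in bp (default 1000).
#' @return A layer-2 \linkS4class{ContigSet} with ids \code{L2|<serial>}.
#' @export
assemblePaths <- function(graph, minFinalLength = 1000L) {
  stopifnot(is(graph, "OverlapGraph"))
  contigs <- graph@contigs
  n <- length(contigs)
  if (!n) return(ContigSet(DNAStringSet(), layer = 2L))
  seqs <- as.character(contigs)
  ids <- names(contigs)
  e <- graph@edges[!graph@edges$reducible, , drop = FALSE]
  outMap <- split(seq_len(nrow(e)), paste(e$from, e$fromOrient))
  inDeg <- table(paste(e$to, e$toOrient))
  getOut <- function(x, o) {
    i <- outMap[[paste(x, o)]]
    if (is.null(i)) integer() else i
  }
  inDegOf <- function(x, o) {
    d <- inDeg[paste(x, o)]
    if (is.na(d)) 0L else as.integer(d)
  }

  visited <- logical(n)
  spellings <- character()
  for (x in order(ids)) {
    if (visited[x]) next
    visited[x] <- TRUE
    walk <- function(start, orient) {
      nodes <- integer(); orients <- integer(); lens <- integer()
      cur <- c(start, orient)
      repeat {
        oe <- getOut(cur[1L], cur[2L])
        if (length(oe) != 1L) break
        nx <- e$to[oe]; no <- e$toOrient[oe]
        if (visited[nx]) break
        if (inDegOf(nx, no) != 1L) break
        visited[nx] <<- TRUE
        nodes <- c(nodes, nx); orients <- c(orients, no)
        lens <- c(lens, e$length[oe])
        cur <- c(nx, no)
      }
      list(nodes = nodes, orients = orients, lens = lens)
    }
    fwd <- walk(x, 0L)
    bwd <- walk(x, 1L)
    # full chain: complement of the backward walk, reversed, then x, then fwd
    chainN <- c(rev(bwd$nodes), x, fwd$nodes)
    chainO <- c(rev(1L - bwd$orients), 0L, fwd$orients)
    chainL <- c(rev(bwd$lens), fwd$lens)
    s <- .orientChr(seqs[chainN[1L]], chainO[1L])
    if (length(chainN) > 1L) {
      for (i in 2L:length(chainN)) {
        nxt <- .orientChr(seqs[chainN[i]], chainO[i])
        s <- paste0(s, substring(nxt, chainL[i - 1L] + 1L))
      }
    }
    rc <- .revcompChr(s)
    spellings <- c(spellings, if (s <= rc) s else rc)
  }
  spellings <- sort(spellings)
  spellings <- spellings[nchar(spellings) >= minFinalLength]
  out <- DNAStringSet(spellings)
  if (length(out)) names(out) <- sprintf("L2|%04d", seq_along(out))
  ContigSet(out, layer = 2L, k = NA_integer_)
}

.orientChr <- function(s, o) if (o == 0L) s else .revcompChr(s)

#' Run the complete second layer
#'
#' Pool, deduplicate, FM-merge, build the overlap graph, transitively reduce
#' it, spell the final contigs and apply the final length filter.
#'
#' @param assemblies list of filtered layer-1 \linkS4class{ContigSet}s.
#' @param minOverlap minimum exact overlap (default 45 bp).
#' @param minFinalLength minimum final contig length (default 1000 bp).
#' @return A layer-2 \linkS4class{ContigSet}.
#' @export
assembleLayer2 <- function(assemblies, minOverlap = 45L,
                           minFinalLength = 1000L) {
  pooled <- poolContigs(assemblies)
  dedup <- removeDuplicates(pooled)
  merged <- fmMerge(dedup, minOverlap)
  graph <- buildOverlapGraph(merged, minOverlap)
  assemblePaths(graph, minFinalLength)
}
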