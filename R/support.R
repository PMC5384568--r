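#' @include AllClasses.R
NULL

#' Map reads back to contigs and count support
#'
#' De Bruijn assembly can chain k-mers from different reads that never
#' co-occur in any single read, producing read-incoherent contigs. This
#' deliberately minimal seed-and-extend aligner (exact seeds, ungapped
#' extension, either strand) decides presence/absence of read support: a
#' read supports a contig when some alignment covers at least
#' \code{minReadCover} of the read at identity at least \code{minIdentity}.
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param contigs a non-empty \linkS4class{ContigSet}.
#' @param minIdentity minimum alignment identity (default 0.95).
#' @param minReadCover minimum covered fraction of the read (default 0.9).
#' @param seedLength exact seed length (default 15).
#' @return data.frame(contigId, supportingReads, bestIdentity), one row per
#'   contig.
#' @export
alignReadsToContigs <- function(reads, contigs, minIdentity = 0.95,
                                minReadCover = 0.9, seedLength = 15L) {
  stopifnot(is(contigs, "ContigSet"))
  if (!length(contigs)) stop("contigs must be non-empty")
  res <- cpp_read_support(.asSeqChar(reads), as.character(contigs),
                          as.integer(seedLength), minIdentity, minReadCover)
  data.frame(contigId = names(contigs),
             supportingReads = as.integer(res$count),
             bestIdentity = as.numeric(res$best_identity),
             stringsAsFactors = FALSE)
}

#' Remove contigs supported by no read
#'
#' Contigs that are not supported by any read are removed; support counts
#' are attached to the survivors. A pure subset operation (sequences are
#' never altered); idempotent.
#'
#' @param contigs a \linkS4class{ContigSet}.
#' @param records support records from \code{\link{alignReadsToContigs}};
#'   every contig must have a record.
#' @return The filtered \linkS4class{ContigSet} with \code{support} filled.
#' @export
filterUnsupported <- function(contigs, records) {
  stopifnot(is(contigs, "ContigSet"))
  if (!length(contigs)) return(contigs)
  idx <- match(names(contigs), records$contigId)
  if (anyNA(idx))
    stop("missing support record for contig(s): ",
         paste(head(names(contigs)[is.na(idx)], 5L), collapse = ", "))
  counts <- records$supportingReads[idx]
  out <- contigs[counts >= 1L]
  mc <- S4Vectors::mcols(out)
  mc$support <- counts[counts >= 1L]
  S4Vectors::mcols(out) <- mc
  out
}
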