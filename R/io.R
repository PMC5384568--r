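#' @include AllClasses.R
NULL

#' Read a paired-end FASTQ library
#'
#' @param r1,r2 paths to the forward/reverse FASTQ files (Phred+33,
#'   optionally gzip-compressed). Read ids are taken up to the first
#'   whitespace and any trailing \code{/1} or \code{/2} is dropped so mates
#'   pair by id.
#' @return list(forward, reverse) of \linkS4class{ReadSet}s.
#' @export
readPairedFastq <- function(r1, r2) {
  fix <- function(x) sub("/[12]$", "", sub("\\s.*$", "", x))
  slurp <- function(path, mate) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(x)$qualities)
    ReadSet(DNAStringSet(setNames(as.character(x), fix(names(x)))), q,
            mate = mate, mode = "RAW")
  }
  list(forward = slurp(r1, "FORWARD"), reverse = slurp(r2, "REVERSE"))
}

#' Write a ReadSet as FASTQ
#'
#' @param reads a \linkS4class{ReadSet}.
#' @param path output path.
#' @param compress write gzip-compressed output.
#' @export
writeReadSet <- function(reads, path, compress = FALSE) {
  Biostrings::writeXStringSet(readSequences(reads), path, format = "fastq",
                              qualities = readQualities(reads),
                              compress = compress)
  invisible(path)
}

#' Write contigs as FASTA
#'
#' Layer-1 headers are \code{L1|k<K>|<serial>}, layer-2 headers
#' \code{L2|<serial>|len=<L>} (the ids already follow this scheme; the
#' length tag is appended for layer-2 contigs).
#'
#' @param contigs a \linkS4class{ContigSet}.
#' @param path output path.
#' @export
writeContigs <- function(contigs, path) {
  out <- DNAStringSet(as.character(contigs))
  nm <- names(contigs)
  layer <- S4Vectors::mcols(contigs)$layer
  is2 <- !is.na(layer) & layer == 2L & !grepl("len=", nm)
  nm[is2] <- paste0(nm[is2], "|len=", BiocGenerics::width(contigs)[is2])
  names(out) <- nm
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read contigs from FASTA
#'
#' Provenance (layer, k) is recovered from \code{L1|k<K>|...} /
#' \code{L2|...} headers when present.
#'
#' @param path FASTA path.
#' @return A \linkS4class{ContigSet}.
#' @export
readContigsFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  layer <- ifelse(grepl("^L2\\|", names(x)), 2L, 1L)
  k <- suppressWarnings(as.integer(sub("^L1\\|k(\\d+)\\|.*$", "\\1",
                                       names(x))))
  ContigSet(x, layer = layer, k = k, support = NA_integer_)
}

#' Read and write repeat annotations as BED (0-based half-open)
#'
#' @param gr a GRanges of repeat intervals with a \code{family} column.
#' @param path BED path.
#' @export
writeRepeatsBed <- function(gr, path) {
  if (length(gr) && !is.null(gr$family)) {
    gr$name <- gr$family
    gr$family <- NULL
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writeRepeatsBed
#' @export
readRepeatsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(gr$name)) {
    gr$family <- gr$name
    gr$name <- NULL
  }
  gr
}

#' Read a reference genome FASTA as an AnnotatedGenome
#'
#' @param path FASTA path (first sequence is used).
#' @param repeats optional BED path with repeat annotations.
#' @return An \linkS4class{AnnotatedGenome}.
#' @export
readReferenceFasta <- function(path, repeats = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  id <- sub("\\s.*$", "", names(x)[1L])
  if (is.null(repeats)) {
    gr <- GenomicRanges::GRanges()
    gr$family <- character(0)
  } else {
    gr <- readRepeatsBed(repeats)
  }
  new("AnnotatedGenome", id = id, sequence = x[[1L]], repeats = gr)
}
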