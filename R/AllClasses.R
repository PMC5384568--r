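#' @include aDNAssembly-package.R
NULL

## ---------------------------------------------------------------- SimConfig

#' Simulation configuration for aDNA-like libraries
#'
#' Holds every parameter of the library simulator: genome composition and
#' planted repeats, the fragment-length model, sequencing layout, error and
#' post-mortem damage rates, the quality model, and the seed. The defaults
#' emulate a typical UDG-untreated short-fragment ancient library: fragments
#' of 44--172 bp (mean 88, sd 20), 101 bp paired-end reads sequenced through
#' the adapter, and C->T deamination decaying geometrically from the fragment
#' ends.
#'
#' @slot genomeLength genome size in bp.
#' @slot repeatSpecs data.frame with columns \code{unitLength},
#'   \code{copies}, \code{divergence} (per-base substitution fraction between
#'   repeat copies, 0 = exact).
#' @slot gcContent GC fraction of the simulated genome.
#' @slot fragmentMin,fragmentMax,fragmentMean,fragmentSd fragment-length
#'   model: normal(\code{fragmentMean}, \code{fragmentSd}) rounded and
#'   clipped to \code{[fragmentMin, fragmentMax]}.
#' @slot targetCoverage fold sequencing coverage (number of genome copies
#'   fragmented).
#' @slot readLength sequenced read length in bp.
#' @slot adapter adapter sequence appended after each fragment (read-through).
#' @slot errorRate per-base substitution sequencing error probability.
#' @slot damageRate5p probability of C->T at the 5'-terminal position (and
#'   G->A at the 3' terminus).
#' @slot damageDecay per-position geometric decay of the damage probability.
#' @slot qualityHigh,qualityLow,coupleErrors two-level quality model: correct
#'   bases get \code{qualityHigh}; when \code{coupleErrors} is TRUE,
#'   erroneous bases get \code{qualityLow}. Padding bases beyond the adapter
#'   always get Q2.
#' @slot seed integer seed; the whole simulation is a pure function of it.
#' @export
setClass("SimConfig", representation(
  genomeLength = "integer",
  repeatSpecs = "data.frame",
  gcContent = "numeric",
  fragmentMin = "integer",
  fragmentMax = "integer",
  fragmentMean = "numeric",
  fragmentSd = "numeric",
  targetCoverage = "numeric",
  readLength = "integer",
  adapter = "character",
  errorRate = "numeric",
  damageRate5p = "numeric",
  damageDecay = "numeric",
  qualityHigh = "integer",
  qualityLow = "integer",
  coupleErrors = "logical",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  p <- c(gc = object@gcContent, err = object@errorRate,
         damage = object@damageRate5p, decay = object@damageDecay)
  if (any(p < 0 | p > 1))
    msg <- c(msg, "gcContent, errorRate, damageRate5p, damageDecay must lie in [0,1]")
  if (object@genomeLength < 1L) msg <- c(msg, "genomeLength must be positive")
  if (object@readLength < 1L) msg <- c(msg, "readLength must be positive")
  if (object@fragmentMin < 1L || object@fragmentMax < object@fragmentMin)
    msg <- c(msg, "need 1 <= fragmentMin <= fragmentMax")
  if (object@fragmentMean < object@fragmentMin ||
      object@fragmentMean > object@fragmentMax)
    msg <- c(msg, "fragmentMean must lie within [fragmentMin, fragmentMax]")
  if (object@targetCoverage < 0) msg <- c(msg, "targetCoverage must be >= 0")
  if (nrow(object@repeatSpecs) &&
      !all(c("unitLength", "copies", "divergence") %in%
           colnames(object@repeatSpecs)))
    msg <- c(msg, "repeatSpecs needs columns unitLength, copies, divergence")
  if (nrow(object@repeatSpecs)) {
    tot <- sum(object@repeatSpecs$unitLength * object@repeatSpecs$copies)
    if (tot >= object@genomeLength)
      msg <- c(msg, "planted repeats do not fit into genomeLength")
    if (any(object@repeatSpecs$divergence < 0 |
            object@repeatSpecs$divergence > 1))
      msg <- c(msg, "repeat divergence must lie in [0,1]")
  }
  if (!is.na(object@adapter) && nchar(object@adapter) &&
      !grepl("^[ACGT]+$", object@adapter))
    msg <- c(msg, "adapter must be a DNA string over ACGT")
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' @param genomeLength,gcContent genome size (bp) and GC fraction.
#' @param repeatSpecs data.frame(unitLength, copies, divergence); one row per
#'   repeat family to plant. Default: none.
#' @param fragmentMin,fragmentMax,fragmentMean,fragmentSd fragment-length
#'   model (bp).
#' @param targetCoverage fold coverage.
#' @param readLength read length (bp).
#' @param adapter adapter sequence (sequenced after short fragments).
#' @param errorRate per-base substitution error probability.
#' @param damageRate5p,damageDecay terminal deamination model; see
#'   \linkS4class{SimConfig}.
#' @param qualityHigh,qualityLow,coupleErrors quality model.
#' @param seed integer seed.
#' @param udg if TRUE, emulate a UDG-treated library by forcing the damage
#'   rate to zero.
#' @return A \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(genomeLength = 5000, targetCoverage = 10, seed = 7)
#' @export
simConfig <- function(genomeLength = 50000,
                      repeatSpecs = data.frame(unitLength = integer(),
                                               copies = integer(),
                                               divergence = numeric()),
                      gcContent = 0.5,
                      fragmentMin = 44, fragmentMax = 172,
                      fragmentMean = 88, fragmentSd = 20,
                      targetCoverage = 30,
                      readLength = 101,
                      adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                      errorRate = 0,
                      damageRate5p = 0.1, damageDecay = 0.5,
                      qualityHigh = 37, qualityLow = 15,
                      coupleErrors = TRUE,
                      seed = 1L,
                      udg = FALSE) {
  if (udg) damageRate5p <- 0
  new("SimConfig",
      genomeLength = as.integer(genomeLength),
      repeatSpecs = as.data.frame(repeatSpecs),
      gcContent = gcContent,
      fragmentMin = as.integer(fragmentMin),
      fragmentMax = as.integer(fragmentMax),
      fragmentMean = fragmentMean, fragmentSd = fragmentSd,
      targetCoverage = targetCoverage,
      readLength = as.integer(readLength),
      adapter = adapter,
      errorRate = errorRate,
      damageRate5p = damageRate5p, damageDecay = damageDecay,
      qualityHigh = as.integer(qualityHigh),
      qualityLow = as.integer(qualityLow),
      coupleErrors = coupleErrors,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@genomeLength, "bp genome,",
      nrow(object@repeatSpecs), "repeat families,",
      sprintf("%gx coverage, fragments %d-%d (mean %g, sd %g), reads %d bp\n",
              object@targetCoverage, object@fragmentMin, object@fragmentMax,
              object@fragmentMean, object@fragmentSd, object@readLength),
      sprintf("  error %g, damage %g (decay %g), seed %d\n",
              object@errorRate, object@damageRate5p, object@damageDecay,
              object@seed))
})

## --------------------------------------------------------- AnnotatedGenome

#' A simulated or reference genome with repeat annotation
#'
#' @slot id sequence identifier.
#' @slot sequence a \link[Biostrings]{DNAString} over ACGT.
#' @slot repeats a \link[GenomicRanges]{GRanges} (1-based, on \code{id}) of
#'   annotated repeat intervals with a \code{family} metadata column.
#' @export
setClass("AnnotatedGenome", representation(
  id = "character",
  sequence = "DNAString",
  repeats = "GRanges"
))

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  freq <- Biostrings::alphabetFrequency(object@sequence)
  if (sum(freq[c("A", "C", "G", "T")]) != length(object@sequence))
    msg <- c(msg, "genome sequence must be over {A,C,G,T}")
  if (length(object@repeats)) {
    if (any(BiocGenerics::start(object@repeats) < 1L) ||
        any(BiocGenerics::end(object@repeats) > length(object@sequence)))
      msg <- c(msg, "repeat intervals must lie within the genome")
    if (is.null(object@repeats$family))
      msg <- c(msg, "repeats need a 'family' metadata column")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname AnnotatedGenome-class
#' @param object,x an \code{AnnotatedGenome}.
#' @export
genomeSeq <- function(x) x@sequence

#' @rdname AnnotatedGenome-class
#' @export
repeatRanges <- function(x) x@repeats

#' @rdname AnnotatedGenome-class
#' @export
genomeId <- function(x) x@id

setMethod("length", "AnnotatedGenome", function(x) length(x@sequence))

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome", object@id, "-", length(object@sequence), "bp,",
      length(object@repeats), "annotated repeat intervals\n")
})

## ------------------------------------------------------------------ ReadSet

.MATE_ROLES <- c("FORWARD", "REVERSE", "MERGED", "SINGLE")
.READ_MODES <- c("RAW", "MERGED", "PAIRED", "COMBINED")

#' A set of sequencing reads with qualities and mate roles
#'
#' Sequences are held as a \link[Biostrings]{DNAStringSet} (names = read
#' ids), qualities as a parallel \link[Biostrings]{PhredQuality}, plus a mate
#' role per read (FORWARD/REVERSE/MERGED/SINGLE) and the preprocessing mode
#' of the whole set (RAW/MERGED/PAIRED/COMBINED). PAIRED sets keep mate pairs
#' under a shared id; MERGED and COMBINED sets must have globally unique ids.
#'
#' @slot sequences DNAStringSet of read sequences.
#' @slot qualities PhredQuality, one string per read, widths matching.
#' @slot mate character vector of mate roles.
#' @slot mode preprocessing mode of the set.
#' @export
setClass("ReadSet", representation(
  sequences = "DNAStringSet",
  qualities = "PhredQuality",
  mate = "character",
  mode = "character"
))

setValidity("ReadSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@qualities) != n)
    msg <- c(msg, "sequences and qualities must have equal length")
  else if (!all(BiocGenerics::width(object@sequences) ==
                BiocGenerics::width(object@qualities)))
    msg <- c(msg, "per-read sequence and quality widths must match")
  if (length(object@mate) != n)
    msg <- c(msg, "one mate role per read required")
  if (!all(object@mate %in% .MATE_ROLES))
    msg <- c(msg, "mate roles must be FORWARD/REVERSE/MERGED/SINGLE")
  if (length(object@mode) != 1L || !(object@mode %in% .READ_MODES))
    msg <- c(msg, "mode must be one of RAW/MERGED/PAIRED/COMBINED")
  if (object@mode %in% c("MERGED", "COMBINED") && n &&
      anyDuplicated(names(object@sequences)))
    msg <- c(msg, paste0(object@mode, " mode requires globally unique read ids"))
  if (object@mode == "PAIRED" && n) {
    ids <- names(object@sequences)
    fwd <- sort(ids[object@mate == "FORWARD"])
    rev <- sort(ids[object@mate == "REVERSE"])
    if (!identical(fwd, rev) || 2L * length(fwd) != n)
      msg <- c(msg, "PAIRED mode must contain complete FORWARD/REVERSE pairs")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReadSet
#'
#' @param sequences DNAStringSet or named character vector of read sequences.
#' @param qualities PhredQuality or character vector of Phred+33 strings; if
#'   missing, constant Q37.
#' @param mate mate role(s), recycled.
#' @param mode preprocessing mode of the set.
#' @return A \linkS4class{ReadSet}.
#' @export
ReadSet <- function(sequences, qualities = NULL, mate = "SINGLE",
                    mode = "RAW") {
  if (!is(sequences, "DNAStringSet")) sequences <- DNAStringSet(sequences)
  if (is.null(qualities)) {
    qualities <- PhredQuality(vapply(BiocGenerics::width(sequences),
      function(w) paste(rep("F", w), collapse = ""), character(1)))
  } else if (!is(qualities, "PhredQuality")) {
    qualities <- PhredQuality(qualities)
  }
  mate <- rep_len(mate, length(sequences))
  new("ReadSet", sequences = sequences, qualities = qualities, mate = mate,
      mode = mode)
}

#' @rdname ReadSet
#' @param x a ReadSet.
#' @export
readSequences <- function(x) x@sequences

#' @rdname ReadSet
#' @export
readQualities <- function(x) x@qualities

#' @rdname ReadSet
#' @export
mateRoles <- function(x) x@mate

#' @rdname ReadSet
#' @export
readMode <- function(x) x@mode

#' @rdname ReadSet
#' @export
readIds <- function(x) names(x@sequences)

setMethod("length", "ReadSet", function(x) length(x@sequences))

setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x, sequences = x@sequences[i], qualities = x@qualities[i],
             mate = x@mate[i])
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet (", object@mode, "): ", length(object), " reads",
      if (length(object)) sprintf(", widths %d-%d",
                                  min(BiocGenerics::width(object@sequences)),
                                  max(BiocGenerics::width(object@sequences))),
      "\n", sep = "")
})

## ---------------------------------------------------------------- ContigSet

#' A set of contigs with provenance and read support
#'
#' A \link[Biostrings]{DNAStringSet} subclass; metadata columns carry
#' provenance (\code{layer} 1 or 2, \code{k} for layer-1 contigs, NA
#' otherwise) and \code{support} (supporting-read count, NA until the
#' read-support filter has run). Names are the contig ids and must be unique.
#'
#' @param seqs DNAStringSet or character vector (named with contig ids).
#' @param layer assembly layer (1 or 2), recycled.
#' @param k k-mer size of the source assembly, NA for layer 2, recycled.
#' @param support supporting-read counts, NA until computed, recycled.
#' @return A \code{ContigSet}.
#' @export
setClass("ContigSet", contains = "DNAStringSet")

setValidity("ContigSet", function(object) {
  msg <- character()
  mc <- S4Vectors::mcols(object)
  if (!all(c("layer", "k", "support") %in% colnames(mc)))
    msg <- c(msg, "metadata columns layer, k, support are required")
  if (length(object) && anyDuplicated(names(object)))
    msg <- c(msg, "contig ids must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname ContigSet-class
#' @export
ContigSet <- function(seqs = DNAStringSet(), layer = 1L, k = NA_integer_,
                      support = NA_integer_) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  n <- length(seqs)
  mc <- S4Vectors::DataFrame(layer = rep_len(as.integer(layer), n),
                             k = rep_len(as.integer(k), n),
                             support = rep_len(as.integer(support), n))
  S4Vectors::mcols(seqs) <- mc
  new("ContigSet", seqs)
}

#' @rdname ContigSet-class
#' @param x a ContigSet.
#' @export
contigProvenance <- function(x) {
  mc <- S4Vectors::mcols(x)
  data.frame(id = names(x), layer = mc$layer, k = mc$k,
             support = mc$support, length = BiocGenerics::width(x),
             stringsAsFactors = FALSE)
}

#' @rdname ContigSet-class
#' @export
contigSupport <- function(x) {
  setNames(S4Vectors::mcols(x)$support, names(x))
}

setMethod("show", "ContigSet", function(object) {
  lay <- unique(S4Vectors::mcols(object)$layer)
  cat("ContigSet: ", length(object), " contigs (layer ",
      paste(lay, collapse = "/"), "), total ",
      sum(BiocGenerics::width(object)), " bp\n", sep = "")
})

## ---------------------------------------------------------------- KmerGraph

#' A canonical k-mer de Bruijn graph
#'
#' Edges are the observed k-mers (held in canonical form, i.e. the
#' lexicographically smaller of the k-mer and its reverse complement) with
#' their multiplicities; nodes are the implied (k-1)-mers. k must be odd so
#' that no k-mer equals its own reverse complement.
#'
#' @slot k odd k-mer size.
#' @slot kmers character vector of canonical k-mers (sorted).
#' @slot counts integer multiplicities, parallel to \code{kmers}.
#' @export
setClass("KmerGraph", representation(
  k = "integer",
  kmers = "character",
  counts = "integer"
))

setValidity("KmerGraph", function(object) {
  msg <- character()
  if (object@k %% 2L == 0L) msg <- c(msg, "k must be odd")
  if (length(object@kmers) != length(object@counts))
    msg <- c(msg, "kmers and counts must be parallel")
  if (length(object@counts) && any(object@counts < 1L))
    msg <- c(msg, "multiplicities must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname KmerGraph-class
#' @param x a KmerGraph.
#' @export
kmerSize <- function(x) x@k

#' @rdname KmerGraph-class
#' @export
kmerCounts <- function(x) setNames(x@counts, x@kmers)

#' @rdname KmerGraph-class
#' @export
graphNodes <- function(x) {
  if (!length(x@kmers)) return(character())
  pre <- substr(x@kmers, 1L, x@k - 1L)
  suf <- substr(x@kmers, 2L, x@k)
  sort(unique(vapply(c(pre, suf), .canonicalChr, character(1), USE.NAMES = FALSE)))
}

setMethod("show", "KmerGraph", function(object) {
  cat("KmerGraph: k =", object@k, "-", length(object@kmers),
      "canonical k-mers, total multiplicity", sum(object@counts), "\n")
})

## ------------------------------------------------------------- OverlapGraph

#' A bidirected exact suffix-prefix overlap (string) graph over contigs
#'
#' Each edge records a maximal exact overlap of at least \code{minOverlap}
#' bp between the 3' end of an oriented contig and the 5' end of another.
#' Edges implied by two consecutive shorter overlaps are flagged
#' \code{reducible} (transitive reduction).
#'
#' @slot contigs the \linkS4class{ContigSet} the graph was built over.
#' @slot edges data.frame(from, fromOrient, to, toOrient, length, reducible).
#' @slot minOverlap minimum overlap length used.
#' @export
setClass("OverlapGraph", representation(
  contigs = "ContigSet",
  edges = "data.frame",
  minOverlap = "integer"
))

#' @rdname OverlapGraph-class
#' @param x an OverlapGraph.
#' @export
overlapEdges <- function(x) x@edges

#' @rdname OverlapGraph-class
#' @export
graphContigs <- function(x) x@contigs

setMethod("show", "OverlapGraph", function(object) {
  cat("OverlapGraph:", length(object@contigs), "contigs,",
      nrow(object@edges), "oriented overlap edges (",
      sum(!object@edges$reducible), "irreducible ), min overlap",
      object@minOverlap, "bp\n")
})

## ----------------------------------------------------------- AssemblyReport

#' Reference-based evaluation bundle for one assembly
#'
#' Contig statistics over mapped contigs of at least the evaluation length
#' cutoff, the reference gap analysis, the coverage-by-minimum-contig-length
#' curve and the unresolved-repeat fraction.
#'
#' @slot label assembly name.
#' @slot nContigs number of contigs passing the length cutoff (mapped).
#' @slot n50,meanLength,longest contig length statistics in bp.
#' @slot nGaps number of maximal uncovered reference intervals.
#' @slot coveredFraction fraction of the reference covered at least once.
#' @slot coverageCurve data.frame(threshold, fraction).
#' @slot repeatUnresolved fraction of annotated repeat bases left in gaps
#'   (NA when no repeats are annotated).
#' @slot gaps GRanges of the uncovered reference intervals.
#' @export
setClass("AssemblyReport", representation(
  label = "character",
  nContigs = "integer",
  n50 = "numeric",
  meanLength = "numeric",
  longest = "numeric",
  nGaps = "integer",
  coveredFraction = "numeric",
  coverageCurve = "data.frame",
  repeatUnresolved = "numeric",
  gaps = "GRanges"
))

setValidity("AssemblyReport", function(object) {
  msg <- character()
  if (object@nContigs > 0L && object@n50 > object@longest)
    msg <- c(msg, "N50 cannot exceed the longest contig")
  if (!is.na(object@coveredFraction) &&
      (object@coveredFraction < 0 || object@coveredFraction > 1))
    msg <- c(msg, "coveredFraction must lie in [0,1]")
  cc <- object@coverageCurve
  if (nrow(cc) > 1L && is.unsorted(rev(cc$fraction)) &&
      any(diff(cc$fraction) > 1e-12))
    msg <- c(msg, "coverage curve must be non-increasing in the threshold")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AssemblyReport", function(object) {
  cat("AssemblyReport [", object@label, "]\n", sep = "")
  cat(sprintf("  contigs >= cutoff: %d | N50 %s | mean %.1f | longest %s\n",
              object@nContigs, format(object@n50, big.mark = ","),
              object@meanLength, format(object@longest, big.mark = ",")))
  cat(sprintf("  gaps: %d | covered: %.1f%% | unresolved repeats: %s\n",
              object@nGaps, 100 * object@coveredFraction,
              if (is.na(object@repeatUnresolved)) "n/a"
              else sprintf("%.1f%%", 100 * object@repeatUnresolved)))
})

## ------------------------------------------------------------ FragmentSet

#' Simulated aDNA fragments with their genomic origin
#'
#' A \link[Biostrings]{DNAStringSet} subclass whose metadata columns record
#' each fragment's origin: genome id, 0-based half-open interval and strand
#' (strand "-" means the fragment sequence is the reverse complement of the
#' genome interval). Sequences may carry deamination damage; the origin
#' always refers to the undamaged genome.
#'
#' @param seqs DNAStringSet or character vector of fragment sequences.
#' @param genome genome id, recycled.
#' @param start,end 0-based half-open origin interval, per fragment.
#' @param strand "+" or "-", per fragment.
#' @return A \code{FragmentSet}.
#' @export
setClass("FragmentSet", contains = "DNAStringSet")

setValidity("FragmentSet", function(object) {
  mc <- S4Vectors::mcols(object)
  msg <- character()
  if (!all(c("genome", "start", "end", "strand") %in% colnames(mc)))
    msg <- c(msg, "metadata columns genome, start, end, strand are required")
  else {
    if (length(object) &&
        !all(mc$end - mc$start == BiocGenerics::width(object)))
      msg <- c(msg, "end - start must equal the fragment length")
    if (length(object) && !all(mc$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FragmentSet-class
#' @export
FragmentSet <- function(seqs = DNAStringSet(), genome = NA_character_,
                        start = integer(), end = integer(),
                        strand = character()) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  n <- length(seqs)
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    genome = rep_len(genome, n), start = as.integer(start),
    end = as.integer(end), strand = strand)
  new("FragmentSet", seqs)
}

#' @rdname FragmentSet-class
#' @param x a FragmentSet.
#' @export
fragmentOrigin <- function(x) {
  mc <- S4Vectors::mcols(x)
  data.frame(id = names(x), genome = mc$genome, start = mc$start,
             end = mc$end, strand = mc$strand, stringsAsFactors = FALSE)
}

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet:", length(object), "fragments",
      if (length(object)) sprintf("(%d-%d bp, mean %.1f)",
                                  min(BiocGenerics::width(object)),
                                  max(BiocGenerics::width(object)),
                                  mean(BiocGenerics::width(object))),
      "\n")
})

## ---------------------------------------------------------------- helpers

.canonicalChr <- function(s) {
  r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (s <= r) s else r
}
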