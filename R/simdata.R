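#' @include AllClasses.R
NULL

.BASES <- c("A", "C", "G", "T")

.baseProbs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

#' Simulate a genome with planted repeat families
#'
#' Draws an i.i.d. background sequence at the configured GC content and
#' plants each repeat family as near-identical copies at non-overlapping
#' random loci (per-copy divergence applied as random substitutions). Every
#' planted copy is recorded in the repeat annotation. The result is a pure
#' function of \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param id genome identifier.
#' @return An \linkS4class{AnnotatedGenome}.
#' @export
simulateGenome <- function(config, id = "sim_genome") {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@genomeLength
  probs <- .baseProbs(config@gcContent)
  genome <- sample(.BASES, n, replace = TRUE, prob = probs)

  occupied <- rep(FALSE, n)
  starts <- integer(); ends <- integer(); fams <- character()
  specs <- config@repeatSpecs
  if (nrow(specs)) {
    for (f in seq_len(nrow(specs))) {
      ulen <- as.integer(specs$unitLength[f])
      copies <- as.integer(specs$copies[f])
      div <- specs$divergence[f]
      unit <- sample(.BASES, ulen, replace = TRUE, prob = probs)
      for (cp in seq_len(copies)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          s <- sample.int(n - ulen + 1L, 1L)
          if (!any(occupied[s:(s + ulen - 1L)])) { placed <- TRUE; break }
        }
        if (!placed)
          stop("repeat placement impossible within genomeLength ",
               "(family ", f, ", copy ", cp, ")")
        copySeq <- unit
        if (div > 0) {
          mut <- which(runif(ulen) < div)
          for (m in mut)
            copySeq[m] <- sample(setdiff(.BASES, copySeq[m]), 1L)
        }
        genome[s:(s + ulen - 1L)] <- copySeq
        occupied[s:(s + ulen - 1L)] <- TRUE
        starts <- c(starts, s); ends <- c(ends, s + ulen - 1L)
        fams <- c(fams, paste0("rep", f))
      }
    }
  }
  rep_gr <- GenomicRanges::GRanges(
    seqnames = rep(id, length(starts)),
    ranges = IRanges::IRanges(start = starts, end = ends),
    family = fams)
  rep_gr <- BiocGenerics::sort(rep_gr)
  new("AnnotatedGenome", id = id,
      sequence = Biostrings::DNAString(paste(genome, collapse = "")),
      repeats = rep_gr)
}

#' Simulate aDNA fragments from a genome
#'
#' Fragments are generated by a molecule-fragmentation model: each of
#' approximately \code{targetCoverage} genome copies is cut into consecutive
#' fragments whose lengths are drawn from the configured normal model,
#' rounded and clipped to \code{[fragmentMin, fragmentMax]}; the terminal
#' remainder of a copy is kept only if it reaches \code{fragmentMin}. The
#' marginal fragment position is near-uniform, the emitted length spectrum
#' follows the configured model, and (unlike interior-only uniform sampling)
#' both genome ends remain covered. Strands are assigned uniformly at
#' random; fragments on "-" carry the reverse complement of the genome
#' interval. Deterministic given the seed.
#'
#' @param genome an \linkS4class{AnnotatedGenome}.
#' @param config a \linkS4class{SimConfig}; \code{fragmentMean} must lie in
#'   \code{[fragmentMin, fragmentMax]}.
#' @return A \linkS4class{FragmentSet}; roughly
#'   \code{targetCoverage * genomeLength / fragmentMean} fragments.
#' @export
simulateFragments <- function(genome, config) {
  stopifnot(is(genome, "AnnotatedGenome"), is(config, "SimConfig"))
  if (config@fragmentMean < config@fragmentMin ||
      config@fragmentMean > config@fragmentMax)
    stop("fragmentMean must lie within [fragmentMin, fragmentMax]")
  set.seed(config@seed + 1L)
  G <- length(genome@sequence)
  copies <- round(config@targetCoverage)
  if (copies < 1L)
    return(FragmentSet(genome = genome@id, start = integer(),
                       end = integer(), strand = character()))
  starts <- integer(); ends <- integer()
  for (cp in seq_len(copies)) {
    pos <- 0L
    while (pos < G) {
      L <- .drawFragLen(1L, config)
      e <- min(pos + L, G)
      if (e - pos >= config@fragmentMin) {
        starts <- c(starts, pos); ends <- c(ends, e)
      }
      pos <- pos + L
    }
  }
  n <- length(starts)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gseq <- genome@sequence
  seqs <- Biostrings::DNAStringSet(gseq,
                                   start = starts + 1L, end = ends)
  flip <- strand == "-"
  if (any(flip)) seqs[flip] <- Biostrings::reverseComplement(seqs[flip])
  names(seqs) <- sprintf("frag%06d", seq_len(n))
  FragmentSet(seqs, genome = genome@id, start = starts, end = ends,
              strand = strand)
}

.drawFragLen <- function(n, config) {
  L <- as.integer(round(rnorm(n, config@fragmentMean, config@fragmentSd)))
  pmax(config@fragmentMin, pmin(config@fragmentMax, L))
}

#' Apply terminal deamination damage to fragments
#'
#' Each cytosine at 5'-offset i is converted to thymine with probability
#' \code{damageRate5p * damageDecay^i}; guanines are converted to adenine
#' symmetrically from the 3' end (the complementary-strand convention).
#' Positions are independent; the result is deterministic given the seed.
#'
#' @param fragments a \linkS4class{FragmentSet}.
#' @param config a \linkS4class{SimConfig}.
#' @return A damaged \linkS4class{FragmentSet} with unchanged origins.
#' @export
applyDamage <- function(fragments, config) {
  stopifnot(is(fragments, "FragmentSet"), is(config, "SimConfig"))
  stopifnot(config@damageRate5p >= 0, config@damageRate5p <= 1,
            config@damageDecay >= 0, config@damageDecay <= 1)
  if (config@damageRate5p == 0 || length(fragments) == 0L) return(fragments)
  set.seed(config@seed + 2L)
  dam <- cpp_apply_damage(as.character(fragments), config@damageRate5p,
                          config@damageDecay)
  out <- Biostrings::DNAStringSet(dam)
  names(out) <- names(fragments)
  mc <- S4Vectors::mcols(fragments)
  FragmentSet(out, genome = mc$genome, start = mc$start, end = mc$end,
              strand = mc$strand)
}

#' Sequence fragments as paired-end reads with adapter read-through
#'
#' The forward read is the first \code{readLength} bases of the fragment,
#' continuing into the adapter and then 'A' padding (at Q2) when the
#' fragment+adapter is shorter than the read; the reverse read is the same
#' construction from the reverse complement of the fragment. Per-base
#' substitution errors are applied at \code{errorRate}; qualities follow the
#' two-level model. Deterministic given the seed.
#'
#' @param fragments a \linkS4class{FragmentSet} (typically after
#'   \code{\link{applyDamage}}).
#' @param config a \linkS4class{SimConfig} with a non-empty adapter.
#' @return list(forward = \linkS4class{ReadSet}, reverse = ReadSet); mates
#'   share the fragment id.
#' @export
sequencePairedEnd <- function(fragments, config) {
  stopifnot(is(fragments, "FragmentSet"), is(config, "SimConfig"))
  if (config@readLength < 1L) stop("readLength must be positive")
  if (!nchar(config@adapter)) stop("adapter_sequence must be non-empty")
  set.seed(config@seed + 3L)
  res <- cpp_sequence_reads(as.character(fragments), config@adapter,
                            config@readLength, config@errorRate,
                            config@qualityHigh, config@qualityLow,
                            config@coupleErrors, 2L)
  ids <- names(fragments)
  fwd <- ReadSet(setNames(res$fwd_seq, ids), res$fwd_qual,
                 mate = "FORWARD", mode = "RAW")
  rev <- ReadSet(setNames(res$rev_seq, ids), res$rev_qual,
                 mate = "REVERSE", mode = "RAW")
  list(forward = fwd, reverse = rev)
}

#' Simulate a complete aDNA-like library
#'
#' Convenience wrapper: genome, fragments, damage, paired-end sequencing and
#' the ground-truth table in one call.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param udg if TRUE, switch deamination off (UDG-treated library).
#' @return list(genome, fragments, forward, reverse, truth) where truth is
#'   the fragment-origin data.frame (read id, genome id, 0-based start, end,
#'   strand).
#' @export
simulateLibrary <- function(config, udg = FALSE) {
  if (udg) config@damageRate5p <- 0
  genome <- simulateGenome(config)
  frags <- simulateFragments(genome, config)
  frags <- applyDamage(frags, config)
  reads <- sequencePairedEnd(frags, config)
  list(genome = genome, fragments = frags,
       forward = reads$forward, reverse = reads$reverse,
       truth = fragmentOrigin(frags))
}

#' Write a simulated library to disk
#'
#' Writes paired FASTQ (Phred+33, \code{_R1.fastq[.gz]} /
#' \code{_R2.fastq[.gz]}), the genome FASTA, the repeat annotation BED
#' (0-based half-open) and the ground-truth TSV of fragment origins.
#'
#' @param lib result of \code{\link{simulateLibrary}}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param gzip compress the FASTQ files.
#' @return Invisibly, the named vector of file paths written.
#' @export
writeSimulatedLibrary <- function(lib, dir, prefix = "sim", gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  r1 <- file.path(dir, paste0(prefix, "_R1", ext))
  r2 <- file.path(dir, paste0(prefix, "_R2", ext))
  writeReadSet(lib$forward, r1, compress = gzip)
  writeReadSet(lib$reverse, r2, compress = gzip)
  fa <- file.path(dir, paste0(prefix, "_genome.fasta"))
  gseq <- Biostrings::DNAStringSet(lib$genome@sequence)
  names(gseq) <- lib$genome@id
  Biostrings::writeXStringSet(gseq, fa)
  bed <- file.path(dir, paste0(prefix, "_repeats.bed"))
  writeRepeatsBed(lib$genome@repeats, bed)
  tsv <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write.table(lib$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(r1 = r1, r2 = r2, genome = fa, repeats = bed, truth = tsv))
}
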