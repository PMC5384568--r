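#' @include AllClasses.R
NULL

#' End-to-end pipeline configuration
#'
#' Either a simulation config (the library is generated) or paths to real
#' paired FASTQ input, together with every numeric default of the
#' preprocessing, assembly, filtering and evaluation stages.
#'
#' @slot sim a \linkS4class{SimConfig}, or NULL when reading FASTQ input.
#' @slot r1,r2 FASTQ paths (ignored when \code{sim} is set).
#' @slot reference optional reference FASTA path (simulated runs evaluate
#'   against the simulated genome).
#' @slot repeats optional repeat-annotation BED path.
#' @slot mode preprocessing mode used for assembly: "merged", "paired" or
#'   "combined".
#' @slot adapter adapter sequence used for clipping.
#' @slot kList odd k-mer sizes of the first layer.
#' @slot minCoverage,maxTipLength layer-1 graph cleaning parameters
#'   (maxTipLength NA = 2k).
#' @slot supportIdentity,supportCover,supportSeed read-support filter
#'   thresholds.
#' @slot minOverlap layer-2 minimum exact overlap (bp).
#' @slot minFinalLength layer-2 final length filter (bp).
#' @slot evalMinLength,evalIdentity evaluation cutoffs.
#' @slot outDir output directory.
#' @slot seed pipeline seed (overrides the sim config seed).
#' @export
setClass("PipelineConfig", representation(
  sim = "ANY",
  r1 = "character", r2 = "character",
  reference = "character", repeats = "character",
  mode = "character",
  adapter = "character",
  kList = "integer",
  minCoverage = "integer", maxTipLength = "integer",
  supportIdentity = "numeric", supportCover = "numeric",
  supportSeed = "integer",
  minOverlap = "integer", minFinalLength = "integer",
  evalMinLength = "integer", evalIdentity = "numeric",
  outDir = "character", seed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!(object@mode %in% c("merged", "paired", "combined")))
    msg <- c(msg, "mode must be merged, paired or combined")
  if (!length(object@kList) || any(object@kList %% 2L == 0L))
    msg <- c(msg, "kList must be non-empty and odd")
  if (is.null(object@sim)) {
    if (is.na(object@r1) || is.na(object@r2))
      msg <- c(msg, "either sim or r1/r2 FASTQ paths are required")
    else if (!file.exists(object@r1) || !file.exists(object@r2))
      msg <- c(msg, "r1/r2 FASTQ files must exist")
  }
  if (any(c(object@minOverlap, object@minFinalLength,
            object@evalMinLength) < 1L))
    msg <- c(msg, "thresholds must be positive")
  if (length(msg)) msg else TRUE
})

#' Build a pipeline configuration
#'
#' @param sim a \linkS4class{SimConfig} (or NULL to read FASTQ).
#' @param r1,r2,reference,repeats input file paths for real data.
#' @param mode,adapter,kList,minCoverage,maxTipLength,supportIdentity,supportCover,supportSeed,minOverlap,minFinalLength,evalMinLength,evalIdentity
#'   stage parameters; see \linkS4class{PipelineConfig}.
#' @param outDir output directory.
#' @param seed pipeline seed.
#' @return A \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = NULL, r1 = NA_character_,
                           r2 = NA_character_,
                           reference = NA_character_,
                           repeats = NA_character_,
                           mode = "merged",
                           adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                           kList = seq(37L, 127L, by = 10L),
                           minCoverage = 2L, maxTipLength = NA_integer_,
                           supportIdentity = 0.95, supportCover = 0.9,
                           supportSeed = 15L,
                           minOverlap = 45L, minFinalLength = 1000L,
                           evalMinLength = 1000L, evalIdentity = 0.9,
                           outDir = tempfile("twolayer_"), seed = 1L) {
  if (!is.null(sim)) {
    sim@seed <- as.integer(seed)
    adapter <- sim@adapter
  }
  new("PipelineConfig", sim = sim, r1 = r1, r2 = r2,
      reference = reference, repeats = repeats, mode = mode,
      adapter = adapter, kList = as.integer(kList),
      minCoverage = as.integer(minCoverage),
      maxTipLength = as.integer(maxTipLength),
      supportIdentity = supportIdentity, supportCover = supportCover,
      supportSeed = as.integer(supportSeed),
      minOverlap = as.integer(minOverlap),
      minFinalLength = as.integer(minFinalLength),
      evalMinLength = as.integer(evalMinLength),
      evalIdentity = evalIdentity,
      outDir = outDir, seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' The YAML document may contain a \code{sim:} block (fields named as the
#' \code{\link{simConfig}} arguments) and any top-level field named as a
#' \code{\link{pipelineConfig}} argument.
#'
#' @param path YAML file path.
#' @param outDir,seed optional overrides.
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path, outDir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$sim)) {
    simArgs <- y$sim
    if (!is.null(simArgs$repeatSpecs))
      simArgs$repeatSpecs <- do.call(rbind, lapply(simArgs$repeatSpecs,
                                                   as.data.frame))
    sim <- do.call(simConfig, simArgs)
  }
  y$sim <- NULL
  if (!is.null(outDir)) y$outDir <- outDir
  if (!is.null(seed)) y$seed <- seed
  known <- names(formals(pipelineConfig))
  y <- y[intersect(names(y), known)]
  do.call(pipelineConfig, c(list(sim = sim), y))
}

#' Run the two-layer assembly pipeline
#'
#' Executes the full workflow: obtain reads (simulate or load), preprocess
#' into the requested mode, run the multi-k first layer, filter
#' read-incoherent contigs, run the overlap-based second layer, and
#' evaluate everything against the reference. All intermediates are written
#' below \code{outDir} and a manifest records parameters, seed and
#' per-stage counts. Rerunning with the same configuration reproduces
#' byte-identical outputs.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param verbose print per-stage progress.
#' @return list(reports = per-assembly \linkS4class{AssemblyReport}s
#'   (layer-1 per k and \code{layer2}), comparison = the comparison table,
#'   layer2 = final \linkS4class{ContigSet}, assemblies = filtered layer-1
#'   sets, manifest = stage-count list, outDir).
#' @export
runTwoLayer <- function(config, verbose = TRUE) {
  stopifnot(is(config, "PipelineConfig"))
  validObject(config)
  say <- function(...) if (verbose) message("[twolayer] ", ...)
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = as.character(packageVersion("aDNAssembly")),
                   seed = config@seed, mode = config@mode,
                   kList = config@kList)

  ## stage 1: input
  if (!is.null(config@sim)) {
    say("simulating library (", config@sim@genomeLength, " bp genome)")
    lib <- simulateLibrary(config@sim)
    writeSimulatedLibrary(lib, file.path(config@outDir, "sim"))
    reference <- lib$genome
    fwd <- lib$forward; rev <- lib$reverse
  } else {
    say("reading FASTQ input")
    rd <- readPairedFastq(config@r1, config@r2)
    fwd <- rd$forward; rev <- rd$reverse
    if (is.na(config@reference))
      stop("config error: a reference FASTA is required for evaluation")
    reference <- readReferenceFasta(config@reference,
                                    repeats = if (is.na(config@repeats))
                                      NULL else config@repeats)
  }
  manifest$readsIn <- length(fwd) + length(rev)

  ## stage 2: preprocessing
  say("preprocessing ", manifest$readsIn, " reads")
  prep <- preprocessReads(fwd, rev, config@adapter)
  reads <- prep[[config@mode]]
  manifest$preprocess <- prep$log
  manifest$readsAssembled <- length(reads)
  dir.create(file.path(config@outDir, "preprocess"), showWarnings = FALSE)
  for (m in c("merged", "paired", "combined"))
    writeReadSet(prep[[m]], file.path(config@outDir, "preprocess",
                                      paste0(m, ".fastq")))
  write.table(prep$log, file.path(config@outDir, "preprocess", "log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: first layer
  say("first layer: k = ", paste(config@kList, collapse = ", "))
  maxTip <- if (is.na(config@maxTipLength)) NULL else config@maxTipLength
  assemblies <- multiKAssemble(reads, config@kList, config@minCoverage,
                               maxTip)
  if (all(vapply(assemblies, length, integer(1)) == 0L))
    stop("stage layer1 failed: no k produced any contig ",
         "(are all k larger than the longest read?)")
  dir.create(file.path(config@outDir, "layer1"), showWarnings = FALSE)
  for (nm in names(assemblies))
    if (length(assemblies[[nm]]))
      writeContigs(assemblies[[nm]],
                   file.path(config@outDir, "layer1",
                             paste0("layer1_", nm, ".fasta")))
  sumTab <- assemblySummary(assemblies)
  write.table(sumTab, file.path(config@outDir, "layer1", "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$layer1 <- sumTab

  ## stage 4: read-support filter
  say("read-support filter")
  supportDir <- file.path(config@outDir, "support")
  dir.create(supportDir, showWarnings = FALSE)
  filtered <- lapply(names(assemblies), function(nm) {
    contigs <- assemblies[[nm]]
    if (!length(contigs)) return(contigs)
    rec <- alignReadsToContigs(reads, contigs, config@supportIdentity,
                               config@supportCover, config@supportSeed)
    write.table(rec, file.path(supportDir, paste0(nm, "_support.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out <- filterUnsupported(contigs, rec)
    if (length(out))
      writeContigs(out, file.path(supportDir,
                                  paste0(nm, "_filtered.fasta")))
    out
  })
  names(filtered) <- names(assemblies)
  manifest$supportKept <- vapply(filtered, length, integer(1))

  ## stage 5: second layer
  say("second layer (min overlap ", config@minOverlap, " bp)")
  layer2 <- assembleLayer2(filtered, config@minOverlap,
                           config@minFinalLength)
  dir.create(file.path(config@outDir, "layer2"), showWarnings = FALSE)
  writeContigs(layer2, file.path(config@outDir, "layer2", "layer2.fasta"))
  manifest$layer2Contigs <- length(layer2)

  ## stage 6: evaluation
  say("evaluation")
  evalDir <- file.path(config@outDir, "evaluate")
  dir.create(evalDir, showWarnings = FALSE)
  reports <- lapply(names(filtered), function(nm)
    assemblyReport(filtered[[nm]], reference, label = paste0("layer1_", nm),
                   minLength = config@evalMinLength,
                   minIdentity = config@evalIdentity))
  names(reports) <- paste0("layer1_", names(filtered))
  reports$layer2 <- assemblyReport(layer2, reference, label = "layer2",
                                   minLength = config@evalMinLength,
                                   minIdentity = config@evalIdentity)
  comparison <- compareAssemblies(reports)
  writeComparison(comparison, file.path(evalDir, "comparison.tsv"))
  writeAssemblyReport(reports$layer2, file.path(evalDir, "layer2_report"))
  yaml::write_yaml(.manifestForYaml(manifest),
                   file.path(config@outDir, "manifest.yaml"))
  say("done: ", length(layer2), " final contigs")
  list(reports = reports, comparison = comparison, layer2 = layer2,
       assemblies = filtered, reference = reference, manifest = manifest,
       outDir = config@outDir)
}

.manifestForYaml <- function(m) {
  lapply(m, function(x) if (is.data.frame(x)) as.list(x) else x)
}

#' Compare assembly reports (Table-style)
#'
#' One row per assembly with the Table-1-shaped metrics; the per-column
#' best value (fewest contigs, highest N50/mean/longest/coverage, fewest
#' gaps, lowest unresolved-repeat fraction) is flagged in the parallel
#' \code{attr(, "best")} logical matrix; ties are all flagged.
#'
#' @param reports a (named) list of at least two
#'   \linkS4class{AssemblyReport}s.
#' @return data.frame with attribute \code{best}.
#' @export
compareAssemblies <- function(reports) {
  if (length(reports) < 2L) stop("need at least two reports to compare")
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(assembly = r@label, nContigs = r@nContigs, n50 = r@n50,
               meanLength = round(r@meanLength, 1), longest = r@longest,
               nGaps = r@nGaps,
               coverage = round(r@coveredFraction, 4),
               repeatUnresolved = round(r@repeatUnresolved, 4),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  higher <- c(nContigs = FALSE, n50 = TRUE, meanLength = TRUE,
              longest = TRUE, nGaps = FALSE, coverage = TRUE,
              repeatUnresolved = FALSE)
  best <- sapply(names(higher), function(cl) {
    v <- tab[[cl]]
    if (all(is.na(v))) return(rep(FALSE, nrow(tab)))
    opt <- if (higher[[cl]]) max(v, na.rm = TRUE) else min(v, na.rm = TRUE)
    !is.na(v) & v == opt
  })
  attr(tab, "best") <- best
  tab
}

#' Write a comparison table as TSV (best values flagged with *)
#'
#' @param comparison result of \code{\link{compareAssemblies}}.
#' @param path output TSV path.
#' @export
writeComparison <- function(comparison, path) {
  best <- attr(comparison, "best")
  out <- comparison
  for (cl in colnames(best)) {
    v <- format(comparison[[cl]])
    v[best[, cl]] <- paste0(v[best[, cl]], "*")
    out[[cl]] <- v
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an assembly report as TSV + JSON
#'
#' @param report an \linkS4class{AssemblyReport}.
#' @param prefix output path prefix (writes \code{<prefix>.tsv},
#'   \code{<prefix>.json}, \code{<prefix>_gaps.bed},
#'   \code{<prefix>_curve.tsv}).
#' @export
writeAssemblyReport <- function(report, prefix) {
  main <- data.frame(
    label = report@label, nContigs = report@nContigs, n50 = report@n50,
    meanLength = report@meanLength, longest = report@longest,
    nGaps = report@nGaps, coveredFraction = report@coveredFraction,
    repeatUnresolved = report@repeatUnresolved)
  write.table(main, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(c(as.list(main),
                         list(coverageCurve = report@coverageCurve)),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  if (length(report@gaps))
    rtracklayer::export(report@gaps, paste0(prefix, "_gaps.bed"),
                        format = "BED")
  write.table(report@coverageCurve, paste0(prefix, "_curve.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
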