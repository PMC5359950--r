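# End-to-end orchestration: config -> sites -> columns -> indels -> genomes
# -> VCF -> reads, with per-stage seed substreams and a JSON manifest.

#' Run the full simulation pipeline
#'
#' Stages, in order: load tree and genome; place variable sites (uniform or
#' clustered); simulate anchor-conditioned columns and assign bases;
#' simulate indel events; build per-tip genomes, the gapped truth
#' alignment, the truth VCF and the event log; simulate paired-end reads
#' per tip. One root seed drives independent per-stage substreams, so
#' adding or removing the read stage never perturbs site placement, and a
#' genomes-only run followed by the read stage reproduces a full run.
#'
#' Output layout under \code{output_dir}:
#' \code{fasta/<tip>/<prefix>_<tip>.fasta},
#' \code{fastq/<tip>/<tip>_R1.fastq.gz} (and _R2),
#' \code{<prefix>.vcf}, \code{<prefix>_events.tsv},
#' \code{<prefix>_alignment_<contig>.fasta},
#' \code{<prefix>_manifest.json}, \code{<prefix>.log}.
#'
#' @param configPath Path to the configuration file (see
#'   \code{\link{parseConfig}}).
#' @param seed Optional integer overriding the config seed; if neither is
#'   set a seed is drawn from entropy and logged.
#' @param outputDir Optional override of the config output directory.
#' @param reads Simulate the read stage (FALSE for genomes-only).
#' @return The run manifest, invisibly (also written as JSON).
#' @export
runSimulation <- function(configPath, seed = NULL, outputDir = NULL,
                          reads = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  config <- parseConfig(configPath)
  if (!is.null(outputDir)) config@outputDir <- outputDir
  rootSeed <- if (!is.null(seed)) as.integer(seed)
              else if (!is.na(config@seed)) config@seed
              else sample.int(.Machine$integer.max, 1L)
  dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config@outputDir, paste0(config@prefix, ".log"))
  logLines <- character(0)
  note <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
    logLines <<- c(logLines, msg)
    message(msg)
  }
  stageTimes <- list()
  timed <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      fatal("stage '", name, "' failed: ", conditionMessage(e)))
    stageTimes[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    r
  }
  note("run starting, seed ", rootSeed)

  tree <- timed("load_tree", loadTree(config@treePath, config@anchorName))
  genome <- timed("load_genome", loadGenome(config@genomePath))
  note("tree: ", nTips(tree), " tips; genome: ", totalLength(genome), " bp")

  freqs <- if (length(config@baseFreqs)) config@baseFreqs else
    baseFrequencies(genome)
  model <- buildGTR(config@gtrRates, freqs)

  set.seed(stageSeed(rootSeed, "sites"))
  plan <- timed("place_sites", if (config@clustering) {
    placeClustered(genome, config@nSites, config@clusteredFraction,
                   config@exponentialMean)
  } else {
    placeUniform(genome, config@nSites)
  })
  note("placed ", nSites(plan), " sites (",
       sum(plan@positions$clustered), " clustered)")

  set.seed(stageSeed(rootSeed, "columns"))
  demand <- table(planAnchorBases(plan, genome))
  pool <- timed("column_pool",
                buildColumnPool(model, tree, setNames(as.integer(demand),
                                                      names(demand))))
  sites <- timed("assign_sites", assignSites(plan, genome, pool, tree))
  note("simulated ", pool$simulated, " columns, kept ", pool$kept,
       " variable")

  set.seed(stageSeed(rootSeed, "indels"))
  events <- timed("indels", simulateIndelEvents(
    tree, config@nSites, config@indelRate, config@indelRate,
    config@lavaletteA, config@lavaletteMax, genome, plan, model))
  note(nrow(events), " indel events (",
       sum(events$kind == "insertion"), " insertions, ",
       sum(events$kind == "deletion"), " deletions)")

  genomes <- timed("genomes", lapply(tipLabels(tree), function(tip)
    buildTipGenome(genome, tip, sites, events)))
  fastaPaths <- writeTipFastas(genomes, config@outputDir, config@prefix)
  vcfPath <- file.path(config@outputDir, paste0(config@prefix, ".vcf"))
  writeTruthVcf(sites, genome, vcfPath)
  evPath <- file.path(config@outputDir, paste0(config@prefix, "_events.tsv"))
  writeEventLog(events, genome, evPath)
  aln <- timed("alignment", buildAlignment(genome, tree, sites, events))
  alnPaths <- writeAlignment(aln, config@outputDir, config@prefix)
  note("wrote ", length(fastaPaths), " genomes, VCF, event log, alignment")

  readCounts <- list()
  if (reads) {
    profile <- readProfile(config@readLength, config@coverage,
                           config@fragmentMean, config@fragmentSd,
                           config@errorModel)
    for (tip in tipLabels(tree)) {
      set.seed(stageSeed(rootSeed, paste0("reads:", tip)))
      g <- genomes[[match(tip, tipLabels(tree))]]
      res <- timed(paste0("reads_", tip),
                   writeReadsForTip(g, profile, config@outputDir))
      readCounts[[tip]] <- list(nPairs = res$nPairs,
                                realizedCoverage =
                                  round(res$realizedCoverage, 4))
    }
    note("read stage complete for ", length(readCounts), " tips")
  } else {
    note("read stage skipped (genomes-only run)")
  }

  manifest <- list(
    software = paste0("anchorsim ",
                      as.character(utils::packageVersion("anchorsim"))),
    config = configPath, seed = rootSeed,
    nTips = nTips(tree), genomeLength = totalLength(genome),
    sitesPlaced = nSites(plan),
    sitesClustered = sum(plan@positions$clustered),
    columnsSimulated = pool$simulated, columnsKept = pool$kept,
    indelEvents = nrow(events),
    insertions = sum(events$kind == "insertion"),
    deletions = sum(events$kind == "deletion"),
    genomesWritten = length(fastaPaths),
    vcf = vcfPath, eventLog = evPath, alignments = as.character(alnPaths),
    readStage = if (reads) "done" else "skipped",
    readPairs = readCounts,
    stageSecondsElapsed = stageTimes,
    totalSecondsElapsed = round(proc.time()[["elapsed"]] - t0, 3))
  manifestPath <- file.path(config@outputDir,
                            paste0(config@prefix, "_manifest.json"))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(logLines, logPath)
  invisible(manifest)
}

#' Run the pipeline without the read stage
#'
#' Stops after FASTA genomes, truth VCF, alignment and event log. Running
#' the read stage later on the same config and seed reproduces the full
#' run's FASTQ, because read-stage seeds are independent substreams.
#'
#' @inheritParams runSimulation
#' @return The run manifest, invisibly.
#' @export
genomesOnly <- function(configPath, seed = NULL, outputDir = NULL) {
  runSimulation(configPath, seed = seed, outputDir = outputDir,
                reads = FALSE)
}

#' Run only the read stage on an existing genomes-only output
#'
#' @param configPath The configuration used for the genomes-only run.
#' @param seed The same root seed; read substreams are derived from it.
#' @param outputDir Optional override matching the earlier run.
#' @return Named list of per-tip read-pair counts, invisibly.
#' @export
readsOnly <- function(configPath, seed = NULL, outputDir = NULL) {
  config <- parseConfig(configPath)
  if (!is.null(outputDir)) config@outputDir <- outputDir
  rootSeed <- if (!is.null(seed)) as.integer(seed)
              else if (!is.na(config@seed)) config@seed
              else fatal("readsOnly requires a seed")
  tree <- loadTree(config@treePath, config@anchorName)
  profile <- readProfile(config@readLength, config@coverage,
                         config@fragmentMean, config@fragmentSd,
                         config@errorModel)
  out <- list()
  for (tip in tipLabels(tree)) {
    safe <- sanitizeLabel(tip)
    fp <- file.path(config@outputDir, "fasta", safe,
                    paste0(config@prefix, "_", safe, ".fasta"))
    if (!file.exists(fp)) fatal("missing tip genome: ", fp)
    contigsTip <- Biostrings::readDNAStringSet(fp)
    # undo the tip suffix added on write so read identifiers match a full run
    names(contigsTip) <- sub(paste0("_", safe, "$"), "",
                             sub("\\s.*$", "", names(contigsTip)))
    g <- new("TipGenome", tipName = tip, contigs = contigsTip,
             provenance = list(nSubstitutions = NA, nEvents = NA))
    set.seed(stageSeed(rootSeed, paste0("reads:", tip)))
    res <- writeReadsForTip(g, profile, config@outputDir)
    out[[tip]] <- res$nPairs
  }
  invisible(out)
}
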